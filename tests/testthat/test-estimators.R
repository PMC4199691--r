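test_that("survival estimators reproduce the worked examples", {
  s_mf <- survival_m_rel_f(76.5, 83.9)
  expect_equal(round(100 - 100 * s_mf, 1), 37.5)          # extra male loss
  expect_equal(s_mf, 0.625, tolerance = 1e-3)
  expect_identical(survival_m_rel_f(60, 60), 1)
  expect_equal(survival_m_rel_f(60, 75), 0.5, tolerance = 1e-12)

  s_yx <- survival_Y_rel_X(76.5)
  expect_equal(round(100 - 100 * s_yx, 1), 69.3)          # extra Y-sperm loss
  expect_equal(s_yx, 0.307, tolerance = 1e-3)
  expect_identical(survival_Y_rel_X(50), 1)
  expect_equal(survival_Y_rel_X(75), 1 / 3, tolerance = 1e-12)

  expect_identical(predicted_pf(1), 50)
  expect_identical(predicted_pf(0), 100)
  expect_equal(round(predicted_pf(0.625), 1), 61.5)

  expect_identical(max_pf_from_total_survival(1), 50)
  expect_equal(max_pf_from_total_survival(0.8), 62.5)
  expect_identical(max_pf_from_total_survival(0.4), 100)
})

test_that("survival estimators reject or flag out-of-domain inputs", {
  expect_error(survival_m_rel_f(0, 50), "between 0 and 100")
  expect_error(survival_m_rel_f(100, 50), "between 0 and 100")
  expect_error(survival_Y_rel_X(45), "against the X")
  expect_error(survival_Y_rel_X(100), "below 100")
  expect_error(predicted_pf(1.5), "\\[0, 1\\]")
  expect_error(max_pf_from_total_survival(0), "\\(0, 1\\]")
  # males surviving better than females: clamped and flagged
  expect_warning(s <- survival_m_rel_f(80, 70), "survived better")
  expect_identical(as.numeric(s), 1)
  expect_identical(attr(s, "flag"), "males_survived_better")
})

test_that("the survival formulas invert the percent-female construction exactly", {
  for (s in seq(0.05, 1, by = 0.05)) {
    # gametic route: E = 100 / (1 + s)
    expect_equal(survival_Y_rel_X(100 / (1 + s)), s, tolerance = 1e-12)
    # zygotic route: F from E and a male post-census survival s
    for (E in c(55, 76.5, 90)) {
      F_ <- 100 * E / (E + (100 - E) * s)
      expect_equal(survival_m_rel_f(E, F_), s, tolerance = 1e-12)
    }
  }
})

test_that("the exact recombination bound behaves as published arithmetic", {
  b <- recombination_upper_bound(354, 0)
  expect_identical(b$point_cM, 0)
  # closed form of the zero-event one-sided exact limit
  expect_equal(b$upper_cM, 200 * (1 - 0.05^(1 / 354)), tolerance = 1e-10)
  expect_equal(round(b$upper_cM, 2), 1.69)
  expect_equal(round(recombination_upper_bound(298, 0)$upper_cM, 1), 2.0)
  # monotone decreasing in the number of informative sires at zero events
  ns <- c(50, 100, 200, 354, 1000)
  ubs <- vapply(ns, function(n) recombination_upper_bound(n, 0)$upper_cM,
                numeric(1))
  expect_true(all(diff(ubs) < 0))
  # all-null-class means free recombination, capped at 50 cM
  all_null <- recombination_upper_bound(100, 100)
  expect_identical(all_null$point_cM, 50)
  expect_true(all_null$unlinked)
  expect_error(recombination_upper_bound(0, 0), "informative")
  expect_error(recombination_upper_bound(10, 11), "n_null_class")
})

test_that("grandson detection probability follows 1 - (1/2)^k", {
  expect_identical(grandson_detection_prob(0), 0)
  expect_identical(grandson_detection_prob(1), 0.5)
  expect_identical(grandson_detection_prob(10), 1 - 1 / 2^10)
  expect_gt(grandson_detection_prob(10), 0.999)
})

test_that("mortality sufficiency compares the F bound against the survival cap", {
  # published bounds: cap 100 * 0.5 / 0.803 = 62.3 < 82.7 -> insufficient
  v <- mortality_sufficiency(list(pf = 83.9, ci_low = 82.7),
                             list(est = 0.84, lo = 0.803))
  expect_identical(as.character(v), "insufficient")
  expect_equal(attr(v, "cap"), 100 * 0.5 / 0.803, tolerance = 1e-12)
  v2 <- mortality_sufficiency(list(pf = 55, ci_low = 52),
                              list(est = 0.85, lo = 0.80))
  expect_identical(as.character(v2), "sufficient")
  v3 <- mortality_sufficiency(list(pf = 50, ci_low = 48),
                              list(est = 0.99, lo = 0.98))
  expect_identical(as.character(v3), "sufficient")
})

test_that("a single vial degenerates to the exact binomial interval", {
  b <- data.frame(n_female = 5L, n_male = 5L)
  est <- sex_ratio_ci(b, "subadult")
  expect_identical(est$method, "exact-binomial")
  expect_identical(est$pf, 50)
  ref <- stats::binom.test(5, 10)$conf.int
  expect_equal(c(est$ci_low, est$ci_high), 100 * ref, tolerance = 1e-10,
               ignore_attr = TRUE)
  # published exact bounds for 5/10 at 95%
  expect_equal(round(c(est$ci_low, est$ci_high), 1), c(18.7, 81.3))
})

test_that("the beta-binomial fit agrees with an independent implementation", {
  skip_if_not_installed("glmmTMB")
  set.seed(77)
  n <- rep(80L, 25)
  mu <- stats::rbeta(25, 76.5 * 0.2, 23.5 * 0.2)  # strong vial heterogeneity
  f <- stats::rbinom(25, n, mu)
  b <- data.frame(n_female = f, n_male = n - f)
  est <- sex_ratio_ci(b, "subadult")
  expect_identical(est$method, "beta-binomial")
  fit <- glmmTMB::glmmTMB(cbind(n_female, n_male) ~ 1, data = b,
                          family = glmmTMB::betabinomial())
  mu_tmb <- 100 * stats::plogis(unname(glmmTMB::fixef(fit)$cond[[1]]))
  expect_equal(est$pf, mu_tmb, tolerance = 1e-3)
  # the point estimate must sit inside its own interval, strictly within the
  # naive pooled bounds under this much heterogeneity
  expect_true(est$ci_low < est$pf && est$pf < est$ci_high)
})

test_that("overdispersion widens the interval beyond the pooled binomial", {
  set.seed(88)
  n <- rep(100L, 20)
  mu <- stats::rbeta(20, 3, 1)
  f <- stats::rbinom(20, n, mu)
  b <- data.frame(n_female = f, n_male = n - f)
  est <- sex_ratio_ci(b, "subadult")
  pooled <- stats::binom.test(sum(f), sum(n))$conf.int * 100
  expect_gt(est$ci_high - est$ci_low, pooled[2] - pooled[1])
})

test_that("interval coverage is near nominal under binomial sampling", {
  p <- mechanism_params(s_Y = 0.307)
  truth <- expected_subadult_pf(p, srxsr)
  set.seed(99)
  hits <- vapply(seq_len(120), function(i) {
    b <- simulate_cross(srxsr, p, n_vials = 10, eggs_per_vial = 60,
                        rho = 0, census = "subadult")
    est <- sex_ratio_ci(b, "subadult")
    est$ci_low <= truth && truth <= est$ci_high
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("empty or degenerate brood input is rejected", {
  expect_error(sex_ratio_ci(data.frame(n_female = 0L, n_male = 0L)),
               "nonzero")
  expect_error(sex_ratio_ci(data.frame(x = 1)), "n_female")
})
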