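test_that("the published seven-cross estimates navigate to SA-ZD", {
  res <- run_screen(published_inputs())
  expect_identical(res$verdict, "SA-ZD-present")
  expect_true(res$has_SD_component)
  expect_identical(nrow(res$trail), 6L)
  expect_true(all(startsWith(res$trail$outcome, "right")))
  expect_equal(res$derived$survival_m_rel_f, 0.625, tolerance = 1e-3)
  expect_equal(res$derived$survival_Y_rel_X, 0.307, tolerance = 1e-3)
  expect_equal(res$derived$predicted_pf, 61.5, tolerance = 2e-3)
})

test_that("equal embryo and subadult bias terminates at step 1", {
  inp <- screen_inputs(
    E = sex_ratio_estimate(75, 74, 76, 5000),
    F_ = sex_ratio_estimate(75.2, 74.3, 76.1, 5000))
  res <- run_screen(inp)
  expect_identical(res$verdict, "SD-or-CYTO-ASEX-only")
  expect_identical(nrow(res$trail), 1L)
})

test_that("each leftward exit fires on its diagnostic pattern", {
  base <- list(
    E = sex_ratio_estimate(50.1, 49.0, 51.2, 5000),
    F_ = sex_ratio_estimate(76.9, 75.6, 78.1, 5000),
    step2a = sex_ratio_estimate(50.2, 49.1, 51.4, 5000),
    step2b = sex_ratio_estimate(76.8, 75.4, 78.0, 5000),
    step3a = sex_ratio_estimate(76.7, 75.3, 78.0, 5000),
    step3b = sex_ratio_estimate(77.0, 75.6, 78.2, 5000),
    step3c = sex_ratio_estimate(50.3, 49.2, 51.5, 5000))
  run_with <- function(...) {
    args <- utils::modifyList(base, list(...))
    run_screen(do.call(screen_inputs, args))
  }
  # the all-rightward pattern: paternal-effect son killing without SD
  expect_identical(run_with()$verdict, "SA-ZD-present")
  expect_false(run_with()$has_SD_component)
  # matriline cross reaches the predicted value: endosymbionts/cyto-fem
  expect_identical(
    run_with(step2a = sex_ratio_estimate(76, 74.6, 77.3, 5000))$verdict,
    "SK-or-CYTO-FEM")
  # patriline cross collapses to 50: recessive autosomal male killer
  expect_identical(
    run_with(step2b = sex_ratio_estimate(50.4, 49.2, 51.6, 5000))$verdict,
    "autosomal-recessive-male-killing")
  # X_SR Y_EVEN sires on focal dams collapse: SK suppressed by the control Y
  expect_identical(
    run_with(step3a = sex_ratio_estimate(51, 49.8, 52.2, 5000))$verdict,
    "SK-suppressed-by-Y_EVEN")
  # same sires on control dams collapse: latent distorter in the control line
  expect_identical(
    run_with(step3b = sex_ratio_estimate(52, 50.8, 53.2, 5000))$verdict,
    "latent-EVEN-distorter")
  # reciprocal backcross female-biased: Y-linked/epistatic killing or fem
  expect_identical(
    run_with(step3c = sex_ratio_estimate(75, 73.6, 76.3, 5000))$verdict,
    "Y_SR-or-epistatic-male-killing-or-sex-chromosome-FEM")
})

test_that("magnitude and significance must both hold for >> and <<", {
  base <- published_inputs()
  # significant but small deviation above 50 at 2a is not '>>'
  expect_identical(run_screen(base)$trail$outcome[2], "right")
  # large deviation with an interval touching 50 is not '>>' either
  inp <- published_inputs()
  inp$step2a <- sex_ratio_estimate(61, 49.5, 72.0, 80)
  expect_identical(run_screen(inp)$verdict, "SA-ZD-present")
  # raising tau above the realized fraction flips an exit to a pass
  sk_inp <- published_inputs()
  sk_inp$step2a <- sex_ratio_estimate(58, 56.5, 59.4, 5000)
  # predicted = 61.5: deviation fraction (58-50)/11.5 = 0.70
  expect_identical(run_screen(sk_inp, screen_config(tau = 0.5))$verdict,
                   "SK-or-CYTO-FEM")
  expect_identical(run_screen(sk_inp, screen_config(tau = 0.8))$verdict,
                   "SA-ZD-present")
})

test_that("missing crosses give an incomplete verdict naming the cross", {
  inp <- published_inputs()
  inp$step3c <- NULL
  res <- run_screen(inp)
  expect_identical(res$verdict, "incomplete")
  expect_identical(res$missing, "step3c")
  expect_match(res$trail$outcome[nrow(res$trail)], "step3c")
})

test_that("the screen is deterministic and ignores estimate entry order", {
  r1 <- run_screen(published_inputs())
  r2 <- run_screen(published_inputs())
  expect_identical(r1$verdict, r2$verdict)
  expect_identical(r1$trail, r2$trail)
  pi <- published_inputs()
  shuffled <- screen_inputs(step3c = pi$step3c, step2b = pi$step2b,
                            E = pi$E, F_ = pi$F, step3b = pi$step3b,
                            step2a = pi$step2a, step3a = pi$step3a)
  expect_identical(run_screen(shuffled)$verdict, r1$verdict)
})

test_that("end-to-end: simulated drive etiologies get the right verdict", {
  # SD + SA-ZD at the published strengths
  ds <- simulate_screen_dataset(
    mechanism_params(s_Y = 0.307, s_son_post = 0.625), seed = 101)
  res <- run_screen(ds)
  expect_identical(res$verdict, "SA-ZD-present")
  expect_true(res$has_SD_component)
  # neutral lines: nothing to explain
  ds0 <- simulate_screen_dataset(mechanism_params(), seed = 102)
  expect_identical(run_screen(ds0)$verdict, "SD-or-CYTO-ASEX-only")
  # son-killing endosymbiont in the focal line exits at the matriline cross
  ds_sk <- simulate_screen_dataset(
    mechanism_params(sk_son_survival = 0.3),
    design = screen_design(sr_line = line_spec("SR", driver = TRUE,
                                               infected = TRUE)),
    seed = 103)
  expect_identical(run_screen(ds_sk)$verdict, "SK-or-CYTO-FEM")
  # recessive male killer: F1 sons on control dams outcross the background
  ds_v <- simulate_screen_dataset(mechanism_params(v_male = 0.3), seed = 104)
  expect_identical(run_screen(ds_v)$verdict,
                   "autosomal-recessive-male-killing")
})

test_that("a control line fixed for a son-rescue suppressor hides zygotic drive", {
  # strong paternal-effect son killing, no sperm killing; the control line
  # carries a dominant autosomal rescue of sons. Expected (and accepted)
  # behaviour: the screen exits leftward, i.e. a false negative, because the
  # patriline cross collapses once sons inherit the rescue allele.
  p <- mechanism_params(
    s_son_post = 0.3,
    suppressors = list(suppressor("rescue", "s_son_post", "offspring")))
  des <- screen_design(even_line = line_spec("EVEN",
                                             aut_suppressors = "rescue"))
  ds <- simulate_screen_dataset(p, design = des, seed = 105)
  res <- run_screen(ds)
  expect_false(res$verdict == "SA-ZD-present")
  # without the suppressed control line the same truth is detected
  ds2 <- simulate_screen_dataset(p, seed = 106)
  expect_identical(run_screen(ds2)$verdict, "SA-ZD-present")
})
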