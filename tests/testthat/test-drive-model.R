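test_that("closed-form expectations reproduce the benchmark sex ratios", {
  # sperm killing alone: %f = 100 / (1 + s_Y)
  expect_equal(expected_embryo_pf(mechanism_params(s_Y = 0.307), srxsr),
               100 / 1.307, tolerance = 1e-12)
  # sequential sperm + son killing at the subadult census
  expect_equal(
    expected_subadult_pf(mechanism_params(s_Y = 0.307, s_son_post = 0.625),
                         srxsr),
    100 / (1 + 0.307 * 0.625), tolerance = 1e-12)
  # neutral parameters give exactly 50 at both stages, in any cross
  for (cr in list(srxsr, evenxeven)) {
    expect_identical(expected_embryo_pf(mechanism_params(), cr), 50)
    expect_identical(expected_subadult_pf(mechanism_params(), cr), 50)
  }
  # an unexpressed driver is inert
  expect_identical(
    expected_embryo_pf(mechanism_params(s_Y = 0.5, penetrance = 0), srxsr),
    50)
  # partial penetrance mixes counts, not ratios
  pen <- 0.8; s <- 0.307
  f <- pen / (1 + s) + (1 - pen) / 2
  m <- pen * s / (1 + s) + (1 - pen) / 2
  expect_equal(
    expected_embryo_pf(mechanism_params(s_Y = s, penetrance = pen), srxsr),
    100 * f / (f + m), tolerance = 1e-12)
})

test_that("a Y-borne suppressor in the sire silences both drive components", {
  p <- mechanism_params(
    s_Y = 0.307, s_son_post = 0.625,
    suppressors = list(suppressor("sec", c("s_Y", "s_son_post"), "sire")))
  supp_sire <- line_genotype(line_spec("SR", driver = TRUE,
                                       y_suppressors = "sec"), "male")
  cr <- cross_spec(supp_sire, line_genotype(sr_line, "female"), "supp")
  expect_identical(expected_subadult_pf(p, cr), 50)
  # the same parameters without the carrier sire still drive
  expect_gt(expected_subadult_pf(p, srxsr), 80)
  # idempotence: declaring the suppressor twice changes nothing
  p2 <- mechanism_params(
    s_Y = 0.307, s_son_post = 0.625,
    suppressors = list(suppressor("sec", c("s_Y", "s_son_post"), "sire"),
                       suppressor("sec", c("s_Y", "s_son_post"), "sire")))
  expect_identical(expected_subadult_pf(p2, cr),
                   expected_subadult_pf(p, cr))
})

test_that("percent-female is non-increasing in every male survival parameter", {
  sr_inf <- line_spec("SR", driver = TRUE, infected = TRUE)
  cr <- cross_spec(line_genotype(sr_inf, "male"),
                   line_genotype(sr_inf, "female"), "SRxSR")
  grid <- seq(0.05, 1, by = 0.05)
  for (par in c("s_Y", "s_son_embryo", "s_son_post", "v_male",
                "sk_son_survival")) {
    pfs <- vapply(grid, function(v) {
      args <- stats::setNames(list(v), par)
      expected_subadult_pf(do.call(mechanism_params, args), cr)
    }, numeric(1))
    expect_true(all(diff(pfs) <= 1e-12),
                info = paste("monotonicity in", par))
  }
})

test_that("sperm killing and zygotic drive compose sequentially", {
  for (a in c(0.2, 0.5, 0.8, 1)) {
    for (b in c(0.3, 0.625, 1)) {
      expect_equal(
        expected_subadult_pf(mechanism_params(s_Y = a, s_son_post = b),
                             srxsr),
        expected_embryo_pf(mechanism_params(s_Y = a * b), srxsr),
        tolerance = 1e-12)
    }
  }
})

test_that("embryo and subadult expectations agree when nothing acts post-census", {
  for (sy in c(0.307, 0.7, 1)) {
    p <- mechanism_params(s_Y = sy, s_son_embryo = 0.9)
    expect_equal(expected_embryo_pf(p, srxsr),
                 expected_subadult_pf(p, srxsr), tolerance = 1e-12)
  }
})

test_that("feminization is counted by the sexing mode", {
  p <- mechanism_params(p_fem_y = 0.3)
  # phenotype sexing sees feminized XY as female already in embryos: E = F
  expect_equal(expected_embryo_pf(p, srxsr, sexing = "phenotype"),
               expected_subadult_pf(p, srxsr), tolerance = 1e-12)
  # karyotype sexing counts them as male: embryos stay at 50
  expect_identical(expected_embryo_pf(p, srxsr, sexing = "karyotype"), 50)
  expect_equal(expected_subadult_pf(p, srxsr), 100 * 0.65 / 1, # f=.5+.15
               tolerance = 1e-12)
})

test_that("son-killing is matrilineal and viability follows the offspring genotype", {
  p_sk <- mechanism_params(sk_son_survival = 0.3)
  inf_sr <- line_spec("SR", infected = TRUE)
  # infected dam: sons die; infected sire line contributes nothing
  cr_dam <- cross_spec(line_genotype(even_line, "male"),
                       line_genotype(inf_sr, "female"), "x")
  cr_sire <- cross_spec(line_genotype(inf_sr, "male"),
                        line_genotype(even_line, "female"), "x")
  expect_equal(expected_subadult_pf(p_sk, cr_dam), 100 * 0.5 / 0.65,
               tolerance = 1e-12)
  expect_identical(expected_subadult_pf(p_sk, cr_sire), 50)

  # recessive male killer on the focal autosomes: inert once outcrossed
  p_v <- mechanism_params(v_male = 0.3)
  expect_equal(expected_subadult_pf(p_v, srxsr), 100 * 0.5 / 0.65,
               tolerance = 1e-12)
  outcross <- cross_spec(line_genotype(sr_line, "male"),
                         line_genotype(even_line, "female"), "x")
  expect_identical(expected_subadult_pf(p_v, outcross), 50)
  # a dominant killer still acts in the heterozygous outcross
  p_dom <- mechanism_params(v_male = 0.3, v_male_dominance = "dominant")
  expect_equal(expected_subadult_pf(p_dom, outcross), 100 * 0.5 / 0.65,
               tolerance = 1e-12)
})

test_that("asexual daughters shift the zygotic ratio", {
  inf <- line_spec("SR", infected = TRUE)
  cr <- cross_spec(line_genotype(even_line, "male"),
                   line_genotype(inf, "female"), "x")
  p <- mechanism_params(asex_fraction = 0.4)
  # f = .4 + .3, m = .3
  expect_equal(expected_subadult_pf(p, cr), 70, tolerance = 1e-12)
  # and embryos show the same bias (left exit at step 1 of the key)
  expect_equal(expected_embryo_pf(p, cr), 70, tolerance = 1e-12)
})

test_that("malformed parameters and crosses are rejected", {
  expect_error(mechanism_params(s_Y = 1.2), "\\[0, 1\\]")
  expect_error(mechanism_params(penetrance = -0.1), "\\[0, 1\\]")
  expect_error(suppressor("x", "not_a_param"), "targets")
  # a female cannot sire a cross
  expect_error(cross_spec(line_genotype(sr_line, "female"),
                          line_genotype(sr_line, "female")), "male")
  expect_error(genotype(character(0)), "at least one X")
  expect_error(genotype(c("A", "B"), c(FALSE, FALSE), y = "A"), "karyotype")
})

test_that("compound-X dams pass their double-X to daughters and their Y to sons", {
  cx_dam <- genotype("sim", y = "sim", compound_x = TRUE,
                     aut_dose = c(sim = 1), cytoplasm = "sim")
  paris_m <- genotype("Paris", x_driver = TRUE, y = "sec",
                      aut_dose = c(sim = 1), cytoplasm = "sim")
  set.seed(1)
  son <- offspring_genotype(paris_m, cx_dam, "male")
  expect_identical(son$x_origin, "Paris")   # X from the sire
  expect_true(son$x_driver)
  expect_identical(son$y, "sim")            # Y from the dam
  daughter <- offspring_genotype(paris_m, cx_dam, "female")
  expect_true(daughter$compound_x)
  expect_identical(daughter$x_origin, "sim")
  expect_identical(daughter$y, "sec")       # sire's Y rides along
})
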