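# Forward simulation of genetic crosses producing per-vial brood counts.
#
# Every stochastic step is a binomial (or beta-binomial) thinning of counts,
# so a vial of any size costs O(1) draws and the pooled expectations match
# the closed forms in expectations.R exactly.

# draw a vial-level probability with mean p and intra-class correlation rho
beta_perturb <- function(p, rho) {
  if (rho <= 0 || p <= 0 || p >= 1) return(p)
  stats::rbeta(1, p * (1 - rho) / rho, (1 - p) * (1 - rho) / rho)
}

simulate_cross_impl <- function(cross, params_for, n_vials, eggs_per_vial,
                                rho, census, base_survival, sexing,
                                eggs_model, vial_prefix = "v") {
  mech <- cross_mechanics(cross, params_for)
  subs <- supp_subsets(mech$off_supp)
  sub_p <- vapply(subs, function(s) s$p, numeric(1))
  rows <- vector("list", n_vials * length(census))
  ri <- 0L
  for (v in seq_len(n_vials)) {
    expressed <- mech$driver && stats::runif(1) < mech$pat$penetrance
    s_Y <- if (expressed) mech$pat$s_Y else 1
    p_male <- (1 - mech$p_asex) * s_Y / (1 + s_Y)
    n_eggs <- as.integer(switch(eggs_model,
                                fixed = eggs_per_vial,
                                poisson = stats::rpois(1, eggs_per_vial)))
    n_m <- stats::rbinom(1L, n_eggs, beta_perturb(p_male, rho))
    n_f <- n_eggs - n_m
    n_fem <- stats::rbinom(1L, n_m, mech$fem_p)
    n_true <- n_m - n_fem
    split <- if (length(subs) == 1L) n_true else
      as.vector(stats::rmultinom(1L, n_true, sub_p))
    alive_emb <- alive_sub <- integer(length(subs))
    for (i in seq_along(subs)) {
      s <- male_survival(mech, expressed, subs[[i]]$carried)
      alive_emb[i] <- stats::rbinom(1L, split[i], beta_perturb(s$embryo, rho))
      alive_sub[i] <- stats::rbinom(1L, alive_emb[i],
                                    beta_perturb(s$post, rho))
    }
    vial_id <- paste0(vial_prefix, v)
    if ("embryo" %in% census) {
      emb_f <- if (sexing == "phenotype") n_f + n_fem else n_f
      emb_m <- sum(alive_emb) + if (sexing == "phenotype") 0L else n_fem
      ri <- ri + 1L
      rows[[ri]] <- data.frame(cross_id = cross$label, vial_id = vial_id,
                               stage = "embryo", n_female = emb_f,
                               n_male = emb_m, n_eggs = n_eggs)
    }
    if ("subadult" %in% census) {
      bs <- beta_perturb(base_survival, rho)
      sub_f <- stats::rbinom(1L, n_f, bs) + stats::rbinom(1L, n_fem, bs)
      sub_m <- stats::rbinom(1L, sum(alive_sub), bs)
      ri <- ri + 1L
      rows[[ri]] <- data.frame(cross_id = cross$label, vial_id = vial_id,
                               stage = "subadult", n_female = sub_f,
                               n_male = sub_m, n_eggs = n_eggs)
    }
  }
  do.call(rbind, rows[seq_len(ri)])
}

#' Simulate brood counts for one cross
#'
#' Forward-simulates per-vial offspring counts under the mechanism model.
#' Each vial holds one sire (drive expression is drawn once per sire), eggs
#' are fertilized with a zygotic male probability set by sperm survival,
#' and male-specific mortality is applied as binomial thinning at the embryo
#' and post-embryo stages. Vial-level heterogeneity is introduced by
#' beta-perturbing the zygote-sex and survival probabilities with intra-class
#' correlation `rho`: `rho = 0` gives pure binomial sampling, larger values
#' inflate the variance of per-vial percent-female without moving the pooled
#' expectation. With `rho = 0` and large totals the pooled stage-wise
#' percent-female converges to [expected_embryo_pf()] /
#' [expected_subadult_pf()].
#'
#' @param cross a [cross_spec()].
#' @param params a [mechanism_params()] object.
#' @param n_vials number of replicate vials (>= 1).
#' @param eggs_per_vial eggs per vial (default 150, a typical cull level
#'   that avoids larval crowding).
#' @param rho intra-vial correlation in `[0, 1)`.
#' @param census stages to census: subset of `c("embryo", "subadult")`.
#' @param base_survival sex-independent egg-to-subadult survival applied to
#'   all offspring after the embryo census (default 1).
#' @param sexing embryo sexing mode, see [expected_embryo_pf()].
#' @param eggs_model `"fixed"` or `"poisson"` eggs per vial.
#' @param seed optional integer seed (set once before simulation).
#' @return a brood-count data.frame with columns `cross_id`, `vial_id`,
#'   `stage`, `n_female`, `n_male`, `n_eggs`.
#' @examples
#' sr <- line_spec("SR", driver = TRUE)
#' cr <- cross_spec(line_genotype(sr, "male"), line_genotype(sr, "female"),
#'                  "SRxSR")
#' b <- simulate_cross(cr, mechanism_params(s_Y = 0.307), n_vials = 12,
#'                     seed = 1)
#' sex_ratio_ci(b, "subadult")
#' @export
simulate_cross <- function(cross, params, n_vials, eggs_per_vial = 150,
                           rho = 0, census = c("embryo", "subadult"),
                           base_survival = 1,
                           sexing = c("phenotype", "karyotype"),
                           eggs_model = c("fixed", "poisson"), seed = NULL) {
  sexing <- match.arg(sexing)
  eggs_model <- match.arg(eggs_model)
  check_pf_args(params, cross)
  if (!is.numeric(rho) || rho < 0 || rho >= 1) {
    stop("'rho' must lie in [0, 1)", call. = FALSE)
  }
  if (eggs_per_vial < 1) stop("'eggs_per_vial' must be >= 1", call. = FALSE)
  if (n_vials < 1) stop("'n_vials' must be >= 1", call. = FALSE)
  census <- match.arg(census, several.ok = TRUE)
  if (!is.null(seed)) set.seed(seed)
  simulate_cross_impl(cross, params_lookup(params), n_vials, eggs_per_vial,
                      rho, census, base_survival, sexing, eggs_model)
}

#' Design of the seven-cross screen experiment
#'
#' Collects the sampling design of the process-of-elimination screen: vial
#' counts and eggs per vial for the subadult censuses, a separate (smaller)
#' set of embryo-census vials for the two parental crosses, the vial-level
#' overdispersion, the sex-independent baseline survival, and the line
#' specifications. Defaults emulate a study in which roughly 1,400 embryos
#' and 5,000-7,000 subadults are sexed per cross.
#'
#' @param n_vials subadult-census vials per cross.
#' @param eggs_per_vial eggs per subadult-census vial.
#' @param embryo_vials embryo-census vials for the parental crosses.
#' @param embryo_eggs eggs per embryo-census vial.
#' @param rho intra-vial correlation of the beta-binomial in `[0, 1)`.
#' @param base_survival sex-independent egg-to-subadult survival.
#' @param sexing embryo sexing mode (`"phenotype"` or `"karyotype"`).
#' @param eggs_model `"fixed"` or `"poisson"`.
#' @param alpha error rate used when turning counts into estimates.
#' @param sr_line,even_line [line_spec()]s for the focal and control lines.
#' @return an object of class `screen_design`.
#' @export
screen_design <- function(n_vials = 40, eggs_per_vial = 150,
                          embryo_vials = 12, embryo_eggs = 120,
                          rho = 0.02, base_survival = 0.92,
                          sexing = c("phenotype", "karyotype"),
                          eggs_model = c("fixed", "poisson"),
                          alpha = 0.05,
                          sr_line = line_spec("SR", driver = TRUE),
                          even_line = line_spec("EVEN")) {
  sexing <- match.arg(sexing)
  eggs_model <- match.arg(eggs_model)
  stopifnot(n_vials >= 1, embryo_vials >= 1, eggs_per_vial >= 1,
            embryo_eggs >= 1, rho >= 0, rho < 1,
            base_survival > 0, base_survival <= 1,
            inherits(sr_line, "sazd_line"), inherits(even_line, "sazd_line"))
  structure(list(n_vials = n_vials, eggs_per_vial = eggs_per_vial,
                 embryo_vials = embryo_vials, embryo_eggs = embryo_eggs,
                 rho = rho, base_survival = base_survival, sexing = sexing,
                 eggs_model = eggs_model, alpha = alpha,
                 sr_line = sr_line, even_line = even_line),
            class = "screen_design")
}

#' Simulate the full seven-cross screen dataset
#'
#' Generates per-vial brood counts for the two parental crosses (embryo and
#' subadult censuses), the two reciprocal F1 crosses, and the three
#' backcrosses of the process-of-elimination screen, deriving F1 sire
#' genotypes by Mendelian transmission (the Y follows the sire's line, the X
#' of an F1 son follows the dam). Mechanism strengths are looked up by line
#' of origin: components derived from the focal line use `params_sr`,
#' components from the control line use `params_even`.
#'
#' @param params_sr [mechanism_params()] for the focal (SR) line.
#' @param params_even [mechanism_params()] for the control (EVEN) line.
#' @param design a [screen_design()].
#' @param seed optional integer seed.
#' @return an object of class `screen_dataset`: a list with `broods` (the
#'   combined brood table), `inputs` (a [screen_inputs()] object estimated
#'   from the counts via [sex_ratio_ci()]), and `design`.
#' @examples
#' ds <- simulate_screen_dataset(
#'   mechanism_params(s_Y = 0.307, s_son_post = 0.625),
#'   design = screen_design(n_vials = 8, embryo_vials = 4), seed = 1)
#' run_screen(ds)
#' @export
simulate_screen_dataset <- function(params_sr,
                                    params_even = mechanism_params(),
                                    design = screen_design(), seed = NULL) {
  stopifnot(inherits(design, "screen_design"))
  validate_mechanism_params(params_sr)
  validate_mechanism_params(params_even)
  if (!is.null(seed)) set.seed(seed)
  sr <- design$sr_line; ev <- design$even_line
  pf <- params_lookup(params_sr, params_even, even_tag = ev$name)
  sr_m <- line_genotype(sr, "male"); sr_f <- line_genotype(sr, "female")
  ev_m <- line_genotype(ev, "male"); ev_f <- line_genotype(ev, "female")
  skt_sr <- params_sr$sk_transmission
  skt_ev <- params_even$sk_transmission
  f1_a <- offspring_genotype(ev_m, sr_f, "male", skt_sr)   # X_SR Y_EVEN
  f1_b <- offspring_genotype(sr_m, ev_f, "male", skt_ev)   # X_EVEN Y_SR

  crosses <- list(
    SRxSR     = cross_spec(sr_m, sr_f, "SRxSR"),
    EVENxEVEN = cross_spec(ev_m, ev_f, "EVENxEVEN"),
    step2a    = cross_spec(ev_m, sr_f, "step2a"),
    step2b    = cross_spec(sr_m, ev_f, "step2b"),
    step3a    = cross_spec(f1_a, sr_f, "step3a"),
    step3b    = cross_spec(f1_a, ev_f, "step3b"),
    step3c    = cross_spec(f1_b, sr_f, "step3c")
  )
  embryo_censused <- c("SRxSR", "EVENxEVEN")
  broods <- list()
  for (nm in names(crosses)) {
    broods[[nm]] <- simulate_cross_impl(
      crosses[[nm]], pf, design$n_vials, design$eggs_per_vial, design$rho,
      census = "subadult", design$base_survival, design$sexing,
      design$eggs_model)
    if (nm %in% embryo_censused) {
      broods[[paste0(nm, "_emb")]] <- simulate_cross_impl(
        crosses[[nm]], pf, design$embryo_vials, design$embryo_eggs,
        design$rho, census = "embryo", design$base_survival, design$sexing,
        design$eggs_model, vial_prefix = "e")
    }
  }
  broods <- do.call(rbind, broods)
  rownames(broods) <- NULL
  inputs <- screen_inputs_from_broods(broods, alpha = design$alpha)
  structure(list(broods = broods, inputs = inputs, design = design),
            class = "screen_dataset")
}

#' Simulate the two-driver recombination assay
#'
#' Forward-simulates the design of the two-point linkage test between two
#' X-linked drivers: grand-offspring sires whose X carries one driver, both,
#' or neither with probabilities set by the map distance; a primary
#' sex-ratio family per sire; and, for sires whose primary family is not
#' significantly female-biased, a follow-up sample of grandson families in
#' which each grandson carries the (possible) driver with probability 1/2.
#'
#' @param r recombination fraction between the two drivers, in `[0, 0.5]`.
#'   Sire classes `driver-A-only`, `driver-B-only`, `both`, `neither` occur
#'   with probabilities `(1-r)/2, (1-r)/2, r/2, r/2`.
#' @param penetrance probability that a carrier sire expresses drive
#'   (re-drawn independently per sire, including grandsons).
#' @param n_sires number of assayed sires.
#' @param dams_per_sire dams mated to each sire (scales the family size).
#' @param family_size mean primary family size per dam; total mean family
#'   size is `dams_per_sire * family_size`.
#' @param family_size_model `"fixed"` or `"poisson"`.
#' @param n_grandsons grandsons tested per followed-up sire.
#' @param grandson_family_size mean grandson family size (total).
#' @param s_Y relative Y-sperm survival of an expressing driver sire
#'   (drives the family percent-female, `100 / (1 + s_Y)`).
#' @param alpha one-sided level of the per-family exact binomial test used
#'   to decide which sires are followed up.
#' @param seed optional integer seed.
#' @return an object of class `linkage_assay_data`: list with `sires`
#'   (data.frame: `sire_id`, `n_female`, `n_male`, `true_class`) and
#'   `grandsons` (data.frame: `sire_id`, `grandson_id`, `n_female`,
#'   `n_male`, `true_carrier`; follow-ups exist only for sires whose
#'   primary family was not significant), plus the generating settings.
#' @examples
#' ad <- simulate_recombination_assay(r = 0, penetrance = 0.9,
#'                                    n_sires = 60, seed = 1)
#' classify_families(ad)
#' @export
simulate_recombination_assay <- function(r, penetrance = 1, n_sires = 400,
                                         dams_per_sire = 2, family_size = 50,
                                         family_size_model = c("fixed",
                                                               "poisson"),
                                         n_grandsons = 10,
                                         grandson_family_size = 80,
                                         s_Y = 0.307, alpha = 0.05,
                                         seed = NULL) {
  family_size_model <- match.arg(family_size_model)
  if (r < 0 || r > 0.5) stop("'r' must lie in [0, 0.5]", call. = FALSE)
  stopifnot(n_sires >= 1, dams_per_sire >= 1, n_grandsons >= 0,
            penetrance >= 0, penetrance <= 1)
  if (!is.null(seed)) set.seed(seed)
  classes <- sample(c("A", "B", "both", "neither"), n_sires, replace = TRUE,
                    prob = c((1 - r) / 2, (1 - r) / 2, r / 2, r / 2))
  mean_n <- dams_per_sire * family_size
  fam_n <- switch(family_size_model,
                  fixed = rep(as.integer(round(mean_n)), n_sires),
                  poisson = stats::rpois(n_sires, mean_n))
  grandson_family_size <- as.integer(round(grandson_family_size))
  expresses <- function(class) {
    n_drivers <- c(A = 1L, B = 1L, both = 2L, neither = 0L)[[class]]
    n_drivers > 0L && stats::runif(1) < 1 - (1 - penetrance)^n_drivers
  }
  pf_expressed <- 1 / (1 + s_Y)
  n_f <- integer(n_sires)
  for (i in seq_len(n_sires)) {
    p <- if (expresses(classes[i])) pf_expressed else 0.5
    n_f[i] <- stats::rbinom(1L, fam_n[i], p)
  }
  sires <- data.frame(sire_id = paste0("s", seq_len(n_sires)),
                      n_female = n_f, n_male = fam_n - n_f,
                      true_class = classes)
  sig <- family_bias_pvalue(n_f, fam_n) < alpha & fam_n > 0
  gs_rows <- list()
  for (i in which(!sig & fam_n > 0)) {
    carrier_sire <- classes[i] != "neither"
    for (g in seq_len(n_grandsons)) {
      carrier <- carrier_sire && stats::runif(1) < 0.5
      expr <- carrier && stats::runif(1) < penetrance
      p <- if (expr) pf_expressed else 0.5
      gf <- stats::rbinom(1L, grandson_family_size, p)
      gs_rows[[length(gs_rows) + 1L]] <- data.frame(
        sire_id = sires$sire_id[i], grandson_id = paste0("g", g),
        n_female = gf, n_male = grandson_family_size - gf,
        true_carrier = carrier)
    }
  }
  grandsons <- if (length(gs_rows)) do.call(rbind, gs_rows) else
    data.frame(sire_id = character(), grandson_id = character(),
               n_female = integer(), n_male = integer(),
               true_carrier = logical())
  structure(list(sires = sires, grandsons = grandsons,
                 settings = list(r = r, penetrance = penetrance,
                                 alpha = alpha, s_Y = s_Y,
                                 n_grandsons = n_grandsons)),
            class = "linkage_assay_data")
}

# one-sided exact binomial p-value for %female > 50, vectorized
family_bias_pvalue <- function(n_female, n_total) {
  p <- rep(1, length(n_female))
  ok <- n_total > 0
  p[ok] <- stats::pbinom(n_female[ok] - 1L, n_total[ok], 0.5,
                         lower.tail = FALSE)
  p
}
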