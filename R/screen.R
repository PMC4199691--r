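#' Configuration of the decision key
#'
#' @param tau magnitude threshold in (0, 1): the fraction of the maximum
#'   possible deviation that must be realized before a comparison counts as
#'   "much greater" (`>>`) or "much less" (`<<`). The key requires *most* of
#'   the possible deviation, operationalized as more than half by default.
#' @param alpha significance level: a deviation must also be supported by
#'   confidence-interval exclusion at this level.
#' @param sexing how embryos were sexed (`"phenotype"` or `"karyotype"`);
#'   recorded in the result because it governs which feminization etiologies
#'   fold into which exits.
#' @return an object of class `screen_config`.
#' @export
screen_config <- function(tau = 0.5, alpha = 0.05,
                          sexing = c("phenotype", "karyotype")) {
  sexing <- match.arg(sexing)
  if (tau <= 0 || tau >= 1) stop("'tau' must lie in (0, 1)", call. = FALSE)
  if (alpha <= 0 || alpha >= 0.5) stop("'alpha' must lie in (0, 0.5)",
                                       call. = FALSE)
  structure(list(tau = tau, alpha = alpha, sexing = sexing),
            class = "screen_config")
}

#' Observations feeding the decision key
#'
#' Bundles the percent-female estimates of the seven-cross design. `E`
#' (embryos of the focal-line cross) and `F` (subadults of the same cross)
#' are required; any later step may be missing, in which case the screen
#' terminates at the last evaluable step with verdict `"incomplete"`.
#'
#' @param E,F_ [sex_ratio_estimate()]s for the focal-line (SR x SR) cross at
#'   the embryo and subadult stage.
#' @param control estimate for the control-line (EVEN x EVEN) subadults.
#' @param step2a estimate for Sire_EVEN x Dam_SR subadults.
#' @param step2b estimate for Sire_SR x Dam_EVEN subadults.
#' @param step3a estimate for X_SR Y_EVEN F1 sires x SR dams.
#' @param step3b estimate for X_SR Y_EVEN F1 sires x EVEN dams.
#' @param step3c estimate for X_EVEN Y_SR F1 sires x SR dams.
#' @param total_survival optional egg-to-subadult total-survival estimate:
#'   list with `est` and `lo` (proportions), used for the
#'   mortality-sufficiency side check.
#' @return an object of class `screen_inputs`.
#' @export
screen_inputs <- function(E, F_, control = NULL, step2a = NULL,
                          step2b = NULL, step3a = NULL, step3b = NULL,
                          step3c = NULL, total_survival = NULL) {
  for (est in list(E, F_)) {
    if (!inherits(est, "sex_ratio_estimate")) {
      stop("'E' and 'F_' must be sex_ratio_estimate objects", call. = FALSE)
    }
  }
  structure(list(E = E, F = F_, control = control, step2a = step2a,
                 step2b = step2b, step3a = step3a, step3b = step3b,
                 step3c = step3c, total_survival = total_survival),
            class = "screen_inputs")
}

#' Build screen inputs from a brood-count table
#'
#' Maps the standard cross labels (`SRxSR`, `EVENxEVEN`, `step2a`, `step2b`,
#' `step3a`, `step3b`, `step3c`) to the estimates the key consumes, running
#' [sex_ratio_ci()] per cross and stage. Missing crosses yield `NULL`
#' entries (the screen then reports an incomplete verdict at that step).
#'
#' @param broods a brood-count data.frame (see [read_brood_table()]).
#' @param alpha two-sided error rate for the intervals.
#' @return a [screen_inputs()] object.
#' @export
screen_inputs_from_broods <- function(broods, alpha = 0.05) {
  est <- function(id, stage) {
    b <- broods[broods$cross_id == id & broods$stage == stage, ]
    if (!nrow(b) || sum(b$n_female + b$n_male) == 0) return(NULL)
    sex_ratio_ci(b, stage, alpha)
  }
  E <- est("SRxSR", "embryo")
  F_ <- est("SRxSR", "subadult")
  if (is.null(E) || is.null(F_)) {
    stop("the brood table must contain cross 'SRxSR' censused at both the ",
         "embryo and subadult stage", call. = FALSE)
  }
  screen_inputs(E, F_, control = est("EVENxEVEN", "subadult"),
                step2a = est("step2a", "subadult"),
                step2b = est("step2b", "subadult"),
                step3a = est("step3a", "subadult"),
                step3b = est("step3b", "subadult"),
                step3c = est("step3c", "subadult"))
}

#' Run the process-of-elimination screen
#'
#' Automates the six-step dichotomous key that classifies the etiology of a
#' female-biased sex ratio. Any step that resolves "to the left" terminates
#' the screen with the corresponding candidate set; navigating rightward
#' through all six steps leaves paternal-effect son killing (SA-ZD) as the
#' only remaining explanation for the post-embryonic component of the bias.
#'
#' The steps, in order:
#' \enumerate{
#'   \item `F` significantly above `E` (CI exclusion)? If not: the bias is
#'     attributable to sperm-level distortion and/or asexuality alone
#'     (verdict `SD-or-CYTO-ASEX-only`). Otherwise the post-embryonic male
#'     survival [survival_m_rel_f()] and its predicted percent-female
#'     [predicted_pf()] are computed.
#'   \item[2a] Matriline cross much above 50 (significant and more than
#'     `tau` of the way to the predicted value)? Exit `SK-or-CYTO-FEM`.
#'   \item[2b] Patriline cross much below `F`? Exit
#'     `autosomal-recessive-male-killing`.
#'   \item[3a] X_SR Y_EVEN sires on focal dams much below `F`? Exit
#'     `SK-suppressed-by-Y_EVEN`.
#'   \item[3b] Same sires on control dams much below `F`? Exit
#'     `latent-EVEN-distorter`.
#'   \item[3c] X_EVEN Y_SR sires on focal dams much above 50 (scale
#'     `F - 50`)? Exit `Y_SR-or-epistatic-male-killing-or-sex-chromosome-FEM`.
#' }
#' All six passed: verdict `SA-ZD-present`, with `has_SD_component` set when
#' the embryo interval already excludes 50 from above.
#'
#' @param inputs a [screen_inputs()] object or a `screen_dataset` from
#'   [simulate_screen_dataset()].
#' @param config a [screen_config()].
#' @return an object of class `screen_result`: `verdict`,
#'   `has_SD_component`, `trail` (one row per evaluated step), and `derived`
#'   (the survival estimates and predicted percent-female).
#' @examples
#' inp <- screen_inputs(
#'   E  = sex_ratio_estimate(76.5, 74.0, 78.7, 1423),
#'   F_ = sex_ratio_estimate(83.9, 82.7, 84.6, 6588),
#'   step2a = sex_ratio_estimate(52.7, 51.1, 54.4, 7013),
#'   step2b = sex_ratio_estimate(84.6, 82.9, 86.2, 5434),
#'   step3a = sex_ratio_estimate(87.3, 85.6, 88.3, 4307),
#'   step3b = sex_ratio_estimate(87.2, 85.6, 88.7, 4692),
#'   step3c = sex_ratio_estimate(53.2, 52.1, 54.3, 4692))
#' run_screen(inp)
#' @export
run_screen <- function(inputs, config = screen_config()) {
  if (inherits(inputs, "screen_dataset")) inputs <- inputs$inputs
  stopifnot(inherits(inputs, "screen_inputs"),
            inherits(config, "screen_config"))
  E <- inputs$E; F_ <- inputs$F
  tau <- config$tau
  trail <- list()
  note <- function(step, comparison, value, reference, outcome) {
    trail[[length(trail) + 1L]] <<- data.frame(
      step = step, comparison = comparison, value = value,
      reference = reference, outcome = outcome)
  }
  finish <- function(verdict, derived = NULL) {
    structure(list(verdict = verdict,
                   has_SD_component = E$ci_low > 50,
                   trail = do.call(rbind, trail),
                   derived = derived, config = config, inputs = inputs),
              class = "screen_result")
  }

  # step 1: does subadult bias exceed embryo bias?
  step1_right <- F_$ci_low > E$ci_high
  note("1", "F significantly > E", F_$pf, E$pf,
       if (step1_right) "right (post-embryonic male loss)" else
         "left (no post-embryonic excess)")
  if (!step1_right) return(finish("SD-or-CYTO-ASEX-only"))

  surv <- suppressWarnings(survival_m_rel_f(E$pf, F_$pf))
  pred <- predicted_pf(as.numeric(surv))
  surv_yx <- if (E$pf >= 50 && E$pf < 100) survival_Y_rel_X(E$pf) else NA_real_
  derived <- list(survival_m_rel_f = as.numeric(surv),
                  survival_Y_rel_X = surv_yx, predicted_pf = pred)

  dev_above <- function(est, scale_top) {
    denom <- max(scale_top - 50, 1e-9)
    est$ci_low > 50 && (est$pf - 50) / denom > tau
  }
  dev_below_F <- function(est) {
    denom <- max(F_$pf - 50, 1e-9)
    est$ci_high < F_$ci_low && (F_$pf - est$pf) / denom > tau
  }
  steps <- list(
    list(id = "2a", est = "step2a",
         cmp = sprintf(">> 50 (scale: predicted %.1f)", pred),
         test = function(e) dev_above(e, pred), ref = 50,
         exit = "SK-or-CYTO-FEM"),
    list(id = "2b", est = "step2b", cmp = "<< F",
         test = dev_below_F, ref = F_$pf,
         exit = "autosomal-recessive-male-killing"),
    list(id = "3a", est = "step3a", cmp = "<< F",
         test = dev_below_F, ref = F_$pf,
         exit = "SK-suppressed-by-Y_EVEN"),
    list(id = "3b", est = "step3b", cmp = "<< F",
         test = dev_below_F, ref = F_$pf,
         exit = "latent-EVEN-distorter"),
    list(id = "3c", est = "step3c",
         cmp = sprintf(">> 50 (scale: F %.1f)", F_$pf),
         test = function(e) dev_above(e, F_$pf), ref = 50,
         exit = "Y_SR-or-epistatic-male-killing-or-sex-chromosome-FEM")
  )
  for (s in steps) {
    est <- inputs[[s$est]]
    if (is.null(est)) {
      note(s$id, s$cmp, NA_real_, s$ref, paste("missing cross", s$est))
      res <- finish("incomplete", derived)
      res$missing <- s$est
      return(res)
    }
    hit <- s$test(est)
    note(s$id, s$cmp, est$pf, s$ref,
         if (hit) paste0("left (", s$exit, ")") else "right")
    if (hit) return(finish(s$exit, derived))
  }
  finish("SA-ZD-present", derived)
}

#' @export
print.screen_result <- function(x, ...) {
  cat("Process-of-elimination screen\n")
  cat("  verdict:          ", x$verdict, "\n")
  cat("  SD component:     ",
      if (isTRUE(x$has_SD_component)) "yes (embryo %♀ already > 50)"
      else "not established", "\n")
  if (!is.null(x$derived)) {
    cat(sprintf("  survival ♂ rel ♀:  %.3f (extra mortality %.1f%%)\n",
                x$derived$survival_m_rel_f,
                100 * (1 - x$derived$survival_m_rel_f)))
    if (!is.na(x$derived$survival_Y_rel_X)) {
      cat(sprintf("  survival Y rel X:  %.3f (extra loss %.1f%%)\n",
                  x$derived$survival_Y_rel_X,
                  100 * (1 - x$derived$survival_Y_rel_X)))
    }
    cat(sprintf("  predicted %%♀:      %.1f\n", x$derived$predicted_pf))
  }
  cat("  trail:\n")
  tr <- x$trail
  for (i in seq_len(nrow(tr))) {
    cat(sprintf("    step %-3s %-34s %6s vs %-6s -> %s\n",
                tr$step[i], tr$comparison[i],
                ifelse(is.na(tr$value[i]), "-",
                       sprintf("%.1f", tr$value[i])),
                sprintf("%.1f", tr$reference[i]), tr$outcome[i]))
  }
  invisible(x)
}
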