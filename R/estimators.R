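#' Post-embryonic male survival relative to females
#'
#' Given the percent-female among embryos (`E`) and among subadults (`F`)
#' from the same cross, returns the survival of males relative to their
#' sisters over the interval between the two censuses:
#' `(100 * E / F - E) / (100 - E)`. The complementary "extra mortality" is
#' `100 * (1 - value)` percent.
#'
#' @param E percent-female among embryos, in (0, 100).
#' @param F_ percent-female among subadults, in (0, 100). Named with a
#'   trailing underscore to avoid masking `base::F`.
#' @return relative survival as a proportion in `[0, 1]`. If `F_ < E`
#'   (males apparently survived better than females) the value is clamped to
#'   1 and carries the attribute `flag = "males_survived_better"`, with a
#'   warning.
#' @examples
#' survival_m_rel_f(76.5, 83.9)   # 0.625; extra male mortality 37.5%
#' @export
survival_m_rel_f <- function(E, F_) {
  stopifnot(is.numeric(E), is.numeric(F_), length(E) == 1L, length(F_) == 1L)
  if (E <= 0 || E >= 100) stop("'E' must lie strictly between 0 and 100",
                               call. = FALSE)
  if (F_ <= 0 || F_ >= 100) stop("'F_' must lie strictly between 0 and 100",
                                 call. = FALSE)
  s <- (100 * E / F_ - E) / (100 - E)
  if (F_ < E) {
    warning("F < E: males survived better than females; survival clamped to 1",
            call. = FALSE)
    s <- structure(1, flag = "males_survived_better")
  }
  s
}

#' Survival of Y-bearing relative to X-bearing sperm
#'
#' Inverts the embryo percent-female of a driver-sire cross into the
#' relative survival/functionality of Y-bearing sperm:
#' `(100 * 50 / E - 50) / 50`, i.e. `100 / E - 1`. The complementary
#' "extra mortality/incapacitation" is `100 * (1 - value)` percent.
#'
#' @param E percent-female among embryos, in `[50, 100)`. Values below 50
#'   indicate drive against the X, outside this screen's scope.
#' @return relative survival as a proportion in `[0, 1]`.
#' @examples
#' survival_Y_rel_X(76.5)   # 0.307; extra Y-sperm loss 69.3%
#' @export
survival_Y_rel_X <- function(E) {
  stopifnot(is.numeric(E), length(E) == 1L)
  if (E >= 100) stop("'E' must be below 100", call. = FALSE)
  if (E < 50) stop("E < 50 indicates drive against the X chromosome, ",
                   "which this screen does not address", call. = FALSE)
  (100 * 50 / E - 50) / 50
}

#' Percent-female predicted from a relative male survival
#'
#' The subadult percent-female expected if the whole sex-ratio bias were
#' produced by the given relative male survival acting on a 50:50 zygotic
#' ratio: `100 / (1 + survival)`.
#'
#' @param survival relative male survival, a proportion in `[0, 1]`.
#' @return percent-female in `[50, 100]`.
#' @examples
#' predicted_pf(0.625)   # 61.5
#' @export
predicted_pf <- function(survival) {
  stopifnot(is.numeric(survival))
  if (any(survival < 0 | survival > 1)) {
    stop("'survival' must lie in [0, 1]", call. = FALSE)
  }
  100 / (1 + survival)
}

#' Maximum percent-female achievable from total mortality alone
#'
#' If the zygotic sex ratio is 50:50 and egg-to-subadult survival is
#' `s_total`, the subadult percent-female cannot exceed
#' `100 * 0.5 / s_total` even if every death is male. Below `s_total = 0.5`
#' all males can be dead and the cap is 100.
#'
#' @param s_total total (both-sex) egg-to-subadult survival, in (0, 1].
#' @return the percent-female cap in `[50, 100]`.
#' @examples
#' max_pf_from_total_survival(0.8)   # 62.5
#' @export
max_pf_from_total_survival <- function(s_total) {
  stopifnot(is.numeric(s_total), length(s_total) == 1L)
  if (s_total <= 0 || s_total > 1) {
    stop("'s_total' must lie in (0, 1]", call. = FALSE)
  }
  if (s_total <= 0.5) return(100)
  100 * 0.5 / s_total
}

#' Can mortality alone explain the observed subadult sex ratio?
#'
#' Compares the lower confidence bound of the subadult percent-female with
#' the largest percent-female that total mortality could produce if every
#' death were male, evaluated at the lower confidence bound of total
#' egg-to-subadult survival. A verdict of `"insufficient"` means mortality
#' alone cannot account for the bias — evidence that a pre-zygotic component
#' (segregation distortion) or another count-distorting mechanism is also
#' acting.
#'
#' @param F_est subadult percent-female estimate: a [sex_ratio_estimate()]
#'   or any list with elements `pf` and `ci_low`.
#' @param survival_est total-survival estimate: a list with elements `est`
#'   and `lo` (proportions), at confidence matched to `F_est`.
#' @return `"insufficient"` or `"sufficient"` (character), with attribute
#'   `cap` giving the percent-female cap used.
#' @examples
#' mortality_sufficiency(list(pf = 83.9, ci_low = 82.7),
#'                       list(est = 0.84, lo = 0.803))  # "insufficient"
#' @export
mortality_sufficiency <- function(F_est, survival_est) {
  f_lo <- F_est$ci_low
  s_lo <- survival_est$lo
  stopifnot(is.numeric(f_lo), is.numeric(s_lo))
  cap <- max_pf_from_total_survival(s_lo)
  verdict <- if (f_lo > cap) "insufficient" else "sufficient"
  structure(verdict, cap = cap)
}

#' Two-point map-distance estimate and exact upper bound
#'
#' In a two-driver recombination assay where only the no-driver recombinant
#' class is detectable, the recombination fraction is estimated as the
#' null-class proportion divided by the detectable fraction of recombinant
#' gametes (1/2 by default: the double-driver class is indistinguishable
#' from single drivers). The upper bound uses the one-sided exact
#' (Clopper-Pearson) binomial limit on the null-class proportion.
#'
#' @param n_informative number of informative sires (produced offspring).
#' @param n_null_class number of sires confirmed to carry no driver.
#' @param alpha one-sided level for the upper bound (default 0.05).
#' @param detect_fraction fraction of recombinant gametes that fall in the
#'   detectable (null) class, default 1/2.
#' @return a list with elements `point_cM`, `upper_cM` (both capped at the
#'   free-recombination limit of 50 cM, with `unlinked = TRUE` set when the
#'   point estimate hits the cap), `n_informative`, `n_null_class`, `alpha`.
#' @examples
#' recombination_upper_bound(354, 0)   # point 0, upper ~1.69 cM
#' @export
recombination_upper_bound <- function(n_informative, n_null_class,
                                      alpha = 0.05, detect_fraction = 0.5) {
  stopifnot(length(n_informative) == 1L, length(n_null_class) == 1L)
  if (n_informative < 1L) stop("no informative sires", call. = FALSE)
  if (n_null_class < 0L || n_null_class > n_informative) {
    stop("'n_null_class' must lie in [0, n_informative]", call. = FALSE)
  }
  if (alpha <= 0 || alpha >= 0.5) stop("'alpha' must lie in (0, 0.5)",
                                       call. = FALSE)
  if (detect_fraction <= 0 || detect_fraction > 1) {
    stop("'detect_fraction' must lie in (0, 1]", call. = FALSE)
  }
  r_point <- (n_null_class / n_informative) / detect_fraction
  # one-sided exact upper limit on the null-class proportion
  p_up <- stats::qbeta(1 - alpha, n_null_class + 1,
                       n_informative - n_null_class)
  r_up <- p_up / detect_fraction
  unlinked <- r_point >= 0.5
  list(point_cM = 100 * min(r_point, 0.5),
       upper_cM = 100 * min(r_up, 0.5),
       unlinked = unlinked,
       n_informative = n_informative, n_null_class = n_null_class,
       alpha = alpha, detect_fraction = detect_fraction)
}

#' Probability that a grandson follow-up detects a heterozygous mother
#'
#' When a dam is heterozygous for an undetected driver, each of her sons
#' carries it with probability 1/2; testing `k` sons detects the driver with
#' probability `1 - (1/2)^k` (assuming every carrier son is detected).
#'
#' @param k number of grandsons tested.
#' @return detection probability in `[0, 1]`.
#' @examples
#' grandson_detection_prob(10)   # 0.9990234 > 0.999
#' @export
grandson_detection_prob <- function(k) {
  stopifnot(is.numeric(k), all(k >= 0), all(k == round(k)))
  1 - 0.5^k
}
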