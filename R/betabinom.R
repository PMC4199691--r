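#' Construct a percent-female estimate
#'
#' Container for a sex-ratio point estimate with its confidence interval.
#' Usually produced by [sex_ratio_ci()]; the constructor is exported so that
#' published estimates can be fed straight into [run_screen()].
#'
#' @param pf percent-female point estimate.
#' @param ci_low,ci_high confidence bounds, `0 <= ci_low <= pf <= ci_high
#'   <= 100`.
#' @param n total offspring sexed.
#' @param n_vials number of replicate vials (NA for literal estimates).
#' @param method `"beta-binomial"`, `"exact-binomial"` or `"literal"`.
#' @param rho estimated intra-vial correlation, if any.
#' @param alpha nominal two-sided error rate of the interval.
#' @return an object of class `sex_ratio_estimate`.
#' @examples
#' sex_ratio_estimate(76.5, 74.0, 78.7, n = 1423)
#' @export
sex_ratio_estimate <- function(pf, ci_low, ci_high, n = NA_integer_,
                               n_vials = NA_integer_, method = "literal",
                               rho = NA_real_, alpha = 0.05) {
  stopifnot(is.numeric(pf), is.numeric(ci_low), is.numeric(ci_high))
  if (!(ci_low >= 0 && ci_low <= pf && pf <= ci_high && ci_high <= 100)) {
    stop("need 0 <= ci_low <= pf <= ci_high <= 100", call. = FALSE)
  }
  structure(list(pf = pf, ci_low = ci_low, ci_high = ci_high,
                 n = n, n_vials = n_vials, method = method,
                 rho = rho, alpha = alpha),
            class = "sex_ratio_estimate")
}

#' @export
print.sex_ratio_estimate <- function(x, ...) {
  cat(sprintf("%%♀ = %.1f, %d%% CI (%.1f, %.1f), n = %s, vials = %s [%s]\n",
              x$pf, round(100 * (1 - x$alpha)), x$ci_low, x$ci_high,
              ifelse(is.na(x$n), "?", x$n),
              ifelse(is.na(x$n_vials), "?", x$n_vials), x$method))
  invisible(x)
}

# beta-binomial log density, mean parameter mu, precision theta
# (intra-class correlation rho = 1 / (1 + theta))
dbetabinom_log <- function(k, n, mu, theta) {
  a <- mu * theta
  b <- (1 - mu) * theta
  lchoose(n, k) + lbeta(k + a, n - k + b) - lbeta(a, b)
}

#' Percent-female estimate with beta-binomial confidence interval
#'
#' Fits an intercept-only beta-binomial model across vials by maximum
#' likelihood, treating the vial as the unit of replication, and returns the
#' percent-female with a profile-likelihood confidence interval. When a
#' single vial is supplied, or when the fitted intra-vial correlation is
#' numerically zero, the estimate degenerates to the pooled exact
#' (Clopper-Pearson) binomial interval.
#'
#' @param broods a brood-count table (see [read_brood_table()] for the
#'   schema), or any data.frame with columns `n_female`, `n_male` and
#'   optionally `stage`.
#' @param stage census stage to use, `"subadult"` or `"embryo"`; ignored if
#'   `broods` has no `stage` column.
#' @param alpha two-sided error rate (default 0.05 for a 95% interval).
#' @return a [sex_ratio_estimate()].
#' @examples
#' b <- data.frame(n_female = c(40, 52, 47), n_male = c(12, 9, 16))
#' sex_ratio_ci(b)
#' @export
sex_ratio_ci <- function(broods, stage = c("subadult", "embryo"),
                         alpha = 0.05) {
  stage <- match.arg(stage)
  stopifnot(is.data.frame(broods))
  if ("stage" %in% names(broods)) broods <- broods[broods$stage == stage, ]
  if (!all(c("n_female", "n_male") %in% names(broods))) {
    stop("'broods' must have columns n_female and n_male", call. = FALSE)
  }
  f <- broods$n_female
  n <- broods$n_female + broods$n_male
  keep <- n > 0
  f <- f[keep]; n <- n[keep]
  if (!length(n)) stop("no vial with a nonzero count at stage '", stage, "'",
                       call. = FALSE)
  nv <- length(n)
  f_tot <- sum(f); n_tot <- sum(n)

  cp <- function() {
    ci <- stats::binom.test(f_tot, n_tot,
                            conf.level = 1 - alpha)$conf.int
    sex_ratio_estimate(100 * f_tot / n_tot, 100 * ci[1], 100 * ci[2],
                       n = n_tot, n_vials = nv, method = "exact-binomial",
                       rho = 0, alpha = alpha)
  }
  if (nv == 1L || f_tot == 0L || f_tot == n_tot) return(cp())

  nll <- function(lmu, ltheta) {
    mu <- stats::plogis(lmu)
    -sum(dbetabinom_log(f, n, mu, exp(ltheta)))
  }
  fit <- stats::optim(c(stats::qlogis(f_tot / n_tot), log(20)),
                      function(p) nll(p[1], p[2]),
                      method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  mu_hat <- stats::plogis(fit$par[1])
  theta_hat <- exp(fit$par[2])
  rho_hat <- 1 / (1 + theta_hat)
  if (rho_hat < 1e-5) return(cp())

  ll_max <- -fit$value
  prof <- function(mu) {
    o <- stats::optimize(function(lt) nll(stats::qlogis(mu), lt),
                         interval = c(-7, 25))
    -o$objective
  }
  crit <- stats::qchisq(1 - alpha, df = 1) / 2
  g <- function(mu) (ll_max - prof(mu)) - crit
  bound <- function(side) {
    lim <- if (side == "low") 1e-6 else 1 - 1e-6
    if (g(lim) <= 0) return(lim)  # likelihood too flat to exclude the edge
    interval <- sort(c(lim, mu_hat))
    stats::uniroot(g, interval = interval, tol = 1e-8)$root
  }
  lo <- min(bound("low"), mu_hat); hi <- max(bound("high"), mu_hat)
  sex_ratio_estimate(100 * mu_hat, 100 * lo, 100 * hi,
                     n = n_tot, n_vials = nv, method = "beta-binomial",
                     rho = rho_hat, alpha = alpha)
}
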