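#' Independence-baseline chi-square
#'
#' Fits the independence model (free variances, all covariances zero) needed
#' as the baseline for CFI and TLI. Its maximum-likelihood solution is
#' available in closed form: the fitted variances equal the sample variances,
#' so \eqn{\chi^2_b = -n \log |R|} with \eqn{R} the sample correlation
#' matrix, on df = p(p-1)/2.
#'
#' @param sample_cov Sample covariance or correlation matrix.
#' @param n Sample size.
#' @return List with `chi2` and `df`.
#' @export
baseline_chi2 <- function(sample_cov, n) {
  R <- stats::cov2cor(as.matrix(sample_cov))
  p <- ncol(R)
  chi2 <- -n * as.numeric(determinant(R, logarithm = TRUE)$modulus)
  list(chi2 = max(chi2, 0), df = p * (p - 1) / 2)
}

#' Chi-square based fit indices
#'
#' Computes CFI, TLI, RMSEA (with 90% noncentral confidence interval) and
#' SRMR for a fitted model. By default the Satorra-Bentler scaled statistics
#' are used when present on the fit (both model and baseline are scaled);
#' `type = "naive"` forces the unscaled statistics.
#'
#' Definitions: \eqn{CFI = 1 - \max(\chi^2-df,0)/\max(\chi^2_b-df_b,
#' \chi^2-df, 0)}; \eqn{TLI = (\chi^2_b/df_b - \chi^2/df)/(\chi^2_b/df_b -
#' 1)}; \eqn{RMSEA = \sqrt{\max(\chi^2-df,0)/(df\,n)}} (denominator
#' \eqn{df\,n}, matching published values computed with the n convention);
#' SRMR is the root mean squared residual between the sample and implied
#' matrices on the correlation metric, over all 66 unique elements including
#' the diagonal.
#'
#' @param fit A converged `bfs_fit`.
#' @param type `"scaled"` (default, falls back to naive when no scaling is
#'   available) or `"naive"`.
#' @param ci_level Confidence level for the RMSEA interval (default .90).
#' @return A `bfs_indices` list: `chi2`, `df`, `cfi`, `tli` (truncated to
#'   \[0, 1\] with raw values in `cfi_raw`/`tli_raw`), `rmsea`, `rmsea_ci90`,
#'   `srmr`, `baseline`, `type`, `n`.
#' @export
compute_indices <- function(fit, type = c("scaled", "naive"),
                            ci_level = 0.90) {
  stopifnot(inherits(fit, "bfs_fit"))
  type <- match.arg(type)
  if (fit$df <= 0) stop("fit indices undefined for a saturated model (df = 0)")
  n <- fit$n
  base <- baseline_chi2(fit$sample$S, n)
  chi2 <- fit$chi2_naive
  chi2_b <- base$chi2
  if (type == "scaled" && !is.null(fit$chi2_scaled)) {
    chi2 <- fit$chi2_scaled
    if (!is.null(fit$baseline_scaling_factor))
      chi2_b <- base$chi2 / fit$baseline_scaling_factor
  } else type <- "naive"

  d <- max(chi2 - fit$df, 0)
  db <- max(chi2_b - base$df, 0)
  cfi_raw <- 1 - (chi2 - fit$df) /
    max(chi2_b - base$df, chi2 - fit$df, .Machine$double.eps)
  cfi <- 1 - d / max(db, d, .Machine$double.eps)
  denom <- chi2_b / base$df - 1
  tli_raw <- if (abs(denom) < .Machine$double.eps) NA_real_ else
    (chi2_b / base$df - chi2 / fit$df) / denom
  tli <- min(max(tli_raw, 0), 1)
  rmsea <- sqrt(d / (fit$df * n))
  ci <- rmsea_ci(chi2, fit$df, n, level = ci_level)

  # SRMR on the correlation metric, diagonal included (66 unique elements)
  Rs <- stats::cov2cor(fit$sample$S)
  Ri <- stats::cov2cor(fit$implied)
  E <- Rs - Ri
  diag(E) <- (diag(fit$sample$S) - diag(fit$implied)) / diag(fit$sample$S)
  srmr <- sqrt(mean(E[lower.tri(E, diag = TRUE)]^2))

  structure(list(chi2 = chi2, df = fit$df, n = n,
                 cfi = min(max(cfi, 0), 1), tli = tli,
                 cfi_raw = cfi_raw, tli_raw = tli_raw,
                 rmsea = rmsea, rmsea_ci90 = ci, srmr = srmr,
                 baseline = list(chi2 = chi2_b, df = base$df),
                 type = type),
            class = "bfs_indices")
}

#' @export
print.bfs_indices <- function(x, ...) {
  cat(sprintf(
    "chi2(%d) = %.2f [%s], CFI = %.3f, TLI = %.3f, SRMR = %.3f,\nRMSEA = %.3f [%.3f, %.3f]\n",
    x$df, x$chi2, x$type, x$cfi, x$tli, x$srmr,
    x$rmsea, x$rmsea_ci90[1], x$rmsea_ci90[2]))
  invisible(x)
}

#' RMSEA noncentral confidence interval
#'
#' Inverts the noncentral chi-square distribution in the noncentrality
#' parameter: the lower bound solves \eqn{P(\chi^2_{df}(\lambda) \le T) =
#' (1+level)/2} and the upper bound \eqn{= (1-level)/2}; each \eqn{\lambda}
#' maps to RMSEA via \eqn{\sqrt{\lambda/(df\,n)}}. Bounds are clipped at 0.
#'
#' @param chi2 Test statistic.
#' @param df Degrees of freedom (> 0).
#' @param n Sample size.
#' @param level Interval level (default .90).
#' @return Numeric vector `c(lower, upper)`.
#' @export
rmsea_ci <- function(chi2, df, n, level = 0.90) {
  stopifnot(df > 0)
  hi <- (1 + level) / 2   # .95 for the lower bound condition
  lo <- (1 - level) / 2   # .05 for the upper bound condition
  solve_ncp <- function(target) {
    if (stats::pchisq(chi2, df, ncp = 0) <= target) return(0)
    upper <- max(chi2 * 2, df + 10)
    while (stats::pchisq(chi2, df, ncp = upper) > target) upper <- upper * 2
    stats::uniroot(function(l) stats::pchisq(chi2, df, ncp = l) - target,
                   c(0, upper), tol = 1e-10)$root
  }
  lam_lo <- solve_ncp(hi)
  lam_hi <- solve_ncp(lo)
  c(sqrt(lam_lo / (df * n)), sqrt(lam_hi / (df * n)))
}

#' Apply goodness-of-fit and model-utility thresholds
#'
#' The screening rule for "model utility": RMSEA < .05, CFI > .95 and
#' TLI > .95 (strict inequalities), and, when an admissibility report is
#' supplied, an admissible solution.
#'
#' @param indices A `bfs_indices`.
#' @param admissibility Optional `bfs_admissibility` report.
#' @param rmsea_lt,cfi_gt,tli_gt Threshold values.
#' @return List of per-criterion logicals plus `overall`.
#' @export
apply_thresholds <- function(indices, admissibility = NULL,
                             rmsea_lt = 0.05, cfi_gt = 0.95, tli_gt = 0.95) {
  stopifnot(inherits(indices, "bfs_indices"))
  out <- list(rmsea = indices$rmsea < rmsea_lt,
              cfi = indices$cfi > cfi_gt,
              tli = indices$tli > tli_gt)
  out$admissible <- if (is.null(admissibility)) NA else
    isTRUE(admissibility$overall_admissible)
  out$overall <- out$rmsea && out$cfi && out$tli &&
    (is.na(out$admissible) || out$admissible)
  out
}
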