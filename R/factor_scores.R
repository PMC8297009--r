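#' Regression (Thomson) factor scores
#'
#' Per-subject latent score estimates
#' \eqn{\hat\eta = \Phi\Lambda'\Sigma^{-1}(x - \mu)} with \eqn{\mu} the
#' *fit's* stored indicator means and \eqn{\Lambda, \Sigma} its estimates on
#' the analyzed covariance metric — so scoring subgroup members with a
#' total-sample fit applies the total-sample weights and centering, never a
#' refit. Bartlett (weighted least squares) scores
#' \eqn{(\Lambda'\Theta^{-1}\Lambda)^{-1}\Lambda'\Theta^{-1}(x - \mu)} are
#' available as a sensitivity option.
#'
#' @param fit A converged `bfs_fit`.
#' @param data n x 11 matrix of indicator scores on the fit's original scale.
#' @param method `"regression"` (default) or `"bartlett"`.
#' @return A `bfs_scores`: matrix n x k with factor-label columns; the fit's
#'   model id and the scoring method are kept as attributes.
#' @export
regression_scores <- function(fit, data,
                              method = c("regression", "bartlett")) {
  stopifnot(inherits(fit, "bfs_fit"))
  method <- match.arg(method)
  X <- as.matrix(data)
  if (!is.null(colnames(X))) X <- X[, fit$spec$indicators, drop = FALSE]
  Z <- sweep(X, 2, fit$sample$means)
  L <- fit$loadings; Phi <- fit$factor_correlations
  if (method == "regression") {
    iSig <- solve(fit$implied)
    Wt <- iSig %*% L %*% Phi          # p x k
  } else {
    if (any(fit$residual_variances <= 0))
      stop("Bartlett scores undefined with non-positive residual variances")
    iTh <- diag(1 / fit$residual_variances, nrow(L))
    Wt <- iTh %*% L %*% solve(t(L) %*% iTh %*% L)
  }
  scores <- Z %*% Wt
  colnames(scores) <- fit$spec$factor_labels
  structure(scores, class = c("bfs_scores", class(scores)),
            model_id = fit$spec$model_id, method = method)
}

#' Standardize factor scores to a reference scale
#'
#' Affine rescale of selected columns to a target mean and SD on the
#' derivation sample (the convention for reporting the p-factor on an
#' IQ-like mean-100 / SD-15 scale). Rank order and all Pearson correlations
#' with other variables are unchanged; the transform applied is recorded in
#' the `"standardization"` attribute.
#'
#' @param scores Matrix of factor scores.
#' @param mean,sd Target mean and SD (defaults 100, 15).
#' @param columns Columns to rescale (default all).
#' @return The rescaled score matrix.
#' @export
standardize_scores <- function(scores, mean = 100, sd = 15,
                               columns = colnames(scores)) {
  out <- scores
  rec <- list()
  for (cn in columns) {
    x <- scores[, cn]
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) stop("constant score column: ", cn)
    out[, cn] <- mean + sd * (x - base::mean(x)) / s
    rec[[cn]] <- c(center = base::mean(x), scale = s,
                   new_mean = mean, new_sd = sd)
  }
  attr(out, "standardization") <- rec
  out
}

#' Correlations between subgroup- and total-sample-derived factor scores
#'
#' For the members of one subgroup, correlates each factor score derived
#' from the subgroup's own fit with each score obtained by applying the
#' total-sample scoring weights to the same subjects.
#'
#' @param subgroup_scores n x k matrix from the subgroup fit.
#' @param total_scores n x k' matrix (same subjects, same row order) from the
#'   total-sample fit.
#' @return Data frame, one row per (subgroup factor, total-sample factor)
#'   pair, with Pearson `r` and two-sided `p_value`.
#' @export
cross_derivation_correlations <- function(subgroup_scores, total_scores) {
  stopifnot(nrow(subgroup_scores) == nrow(total_scores))
  .cor_table(subgroup_scores, total_scores,
             names_a = "subgroup_factor", names_b = "total_factor")
}

#' Correlations between factor scores and covariates
#'
#' Pearson correlations of each factor score column with each covariate,
#' with two-sided p-values and the conventional significance stars
#' (`*` p < .05, `**` p < .01).
#'
#' @param scores n x k matrix of factor scores.
#' @param covariates n x m matrix of covariates, same subjects/rows.
#' @return Data frame with columns `factor`, `covariate`, `r`, `p_value`,
#'   `stars`.
#' @export
covariate_correlations <- function(scores, covariates) {
  stopifnot(nrow(scores) == nrow(covariates))
  out <- .cor_table(scores, covariates,
                    names_a = "factor", names_b = "covariate")
  out$stars <- ifelse(out$p_value < 0.01, "**",
                      ifelse(out$p_value < 0.05, "*", ""))
  out
}

.cor_table <- function(A, B, names_a, names_b) {
  A <- as.matrix(A); B <- as.matrix(B)
  n <- nrow(A)
  if (is.null(colnames(A))) colnames(A) <- paste0("a", seq_len(ncol(A)))
  if (is.null(colnames(B))) colnames(B) <- paste0("b", seq_len(ncol(B)))
  if (any(apply(A, 2, stats::sd) == 0) || any(apply(B, 2, stats::sd) == 0))
    stop("degenerate (constant) column")
  r <- stats::cor(A, B)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  pv <- 2 * stats::pt(-abs(tstat), df = n - 2)
  pv[abs(r) >= 1] <- 0
  out <- expand.grid(a = colnames(A), b = colnames(B),
                     stringsAsFactors = FALSE)
  out$r <- as.vector(r)
  out$p_value <- as.vector(pv)
  names(out)[1:2] <- c(names_a, names_b)
  out
}
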