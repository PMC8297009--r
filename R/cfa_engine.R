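# ---- internal parameter packing -------------------------------------------

.cfa_layout <- function(spec) {
  pat <- spec$loading_pattern
  k <- ncol(pat)
  phi_idx <- matrix(0L, nrow(spec$free_factor_correlations), 2)
  if (nrow(phi_idx)) {
    phi_idx[, 1] <- match(spec$free_factor_correlations[, 1],
                          spec$factor_labels)
    phi_idx[, 2] <- match(spec$free_factor_correlations[, 2],
                          spec$factor_labels)
  }
  nl <- sum(pat); nph <- nrow(phi_idx); p <- nrow(pat)
  list(pat = pat, k = k, p = p, nl = nl, nph = nph, phi_idx = phi_idx,
       q = nl + nph + p)
}

.cfa_unpack <- function(theta, lay) {
  L <- matrix(0, lay$p, lay$k, dimnames = dimnames(lay$pat))
  L[lay$pat] <- theta[seq_len(lay$nl)]
  Phi <- diag(lay$k)
  if (lay$nph) for (r in seq_len(lay$nph)) {
    v <- theta[lay$nl + r]
    Phi[lay$phi_idx[r, 1], lay$phi_idx[r, 2]] <- v
    Phi[lay$phi_idx[r, 2], lay$phi_idx[r, 1]] <- v
  }
  Th <- theta[lay$nl + lay$nph + seq_len(lay$p)]
  list(L = L, Phi = Phi, Th = Th)
}

.cfa_sigma <- function(m) {
  S <- m$L %*% m$Phi %*% t(m$L) + diag(m$Th, length(m$Th))
  (S + t(S)) / 2
}

# F_ML = log|Sigma| + tr(S Sigma^-1) - log|S| - p
.cfa_objective <- function(theta, lay, S, logdetS) {
  m <- .cfa_unpack(theta, lay)
  Sig <- .cfa_sigma(m)
  ch <- tryCatch(chol(Sig), error = function(e) NULL)
  if (is.null(ch)) return(1e10)
  iSig <- chol2inv(ch)
  val <- 2 * sum(log(diag(ch))) + sum(iSig * S) - logdetS - lay$p
  if (!is.finite(val)) 1e10 else val
}

.cfa_gradient <- function(theta, lay, S, logdetS) {
  m <- .cfa_unpack(theta, lay)
  Sig <- .cfa_sigma(m)
  ch <- tryCatch(chol(Sig), error = function(e) NULL)
  if (is.null(ch)) ch <- chol(Sig + diag(1e-6, lay$p))
  iSig <- chol2inv(ch)
  W <- iSig - iSig %*% S %*% iSig
  gL <- 2 * (W %*% m$L %*% m$Phi)
  g <- gL[lay$pat]
  if (lay$nph) {
    gP <- t(m$L) %*% W %*% m$L
    g <- c(g, vapply(seq_len(lay$nph), function(r)
      2 * gP[lay$phi_idx[r, 1], lay$phi_idx[r, 2]], 0))
  }
  c(g, diag(W))
}

# canonical sign convention: each factor's loading sum is nonnegative
.cfa_fix_signs <- function(m, lay) {
  for (f in seq_len(lay$k)) {
    if (sum(m$L[, f]) < 0) {
      m$L[, f] <- -m$L[, f]
      m$Phi[f, -f] <- -m$Phi[f, -f]
      m$Phi[-f, f] <- -m$Phi[-f, f]
    }
  }
  m
}

# Jacobian of vech(Sigma) wrt free parameters, 66 x q
.cfa_delta <- function(m, lay) {
  p <- lay$p
  low <- lower.tri(diag(p), diag = TRUE)
  cols <- vector("list", lay$q)
  PhiLt <- m$Phi %*% t(m$L)              # k x p
  pos <- which(lay$pat, arr.ind = TRUE)
  for (r in seq_len(lay$nl)) {
    i <- pos[r, 1]; f <- pos[r, 2]
    M <- matrix(0, p, p)
    M[i, ] <- M[i, ] + PhiLt[f, ]
    M[, i] <- M[, i] + PhiLt[f, ]
    cols[[r]] <- M[low]
  }
  if (lay$nph) for (r in seq_len(lay$nph)) {
    a <- m$L[, lay$phi_idx[r, 1]]; b <- m$L[, lay$phi_idx[r, 2]]
    M <- outer(a, b); M <- M + t(M)
    cols[[lay$nl + r]] <- M[low]
  }
  for (i in seq_len(p)) {
    M <- matrix(0, p, p); M[i, i] <- 1
    cols[[lay$nl + lay$nph + i]] <- M[low]
  }
  do.call(cbind, cols)
}

# normal-theory weight matrix 0.5 D'(iSig x iSig)D at the fitted moments
.cfa_weight <- function(iSig) {
  D <- .duplication(nrow(iSig))
  0.5 * t(D) %*% (iSig %x% iSig) %*% D
}

# ---- public API -----------------------------------------------------------

#' Fit a structural model by maximum likelihood
#'
#' Minimizes the normal-theory discrepancy
#' \eqn{F_{ML} = \log|\Sigma(\theta)| + tr(S\Sigma(\theta)^{-1}) - \log|S| - p}
#' over the model's free loadings, factor correlations and residual variances
#' (factor variances fixed to 1). The analyzed moments are the ML
#' (divisor-n) covariance matrix; internally the optimizer works on the
#' correlation metric, where the default start values are well scaled, and
#' the solution is mapped back by rescaling (the models are scale invariant,
#' so the discrepancy is unchanged). Residual variances are unconstrained,
#' so Heywood cases surface as negative estimates rather than boundary
#' solutions, and are caught by [check_admissibility()].
#'
#' The naive test statistic is \eqn{\chi^2 = n \cdot F_{ML}} (multiplier n,
#' which reproduces published RMSEA values computed with an n denominator).
#' When raw data are supplied, Satorra-Bentler mean-scaled statistics and
#' sandwich standard errors are added via [robust_corrections()].
#'
#' @param spec A `bfs_model` template.
#' @param data n x 11 numeric matrix or data frame of raw indicator scores
#'   (columns matched to `spec$indicators` by name when named).
#' @param sample_cov Alternatively, a positive-definite covariance or
#'   correlation matrix.
#' @param n Sample size (required with `sample_cov`).
#' @param robust Compute Satorra-Bentler corrections when raw data are
#'   available (default TRUE).
#' @param start Optional start vector; defaults to loadings .5, correlations
#'   0, residual variances .5.
#' @param max_iter Optimizer iteration cap (default 500).
#' @param grad_tol Largest absolute gradient element accepted as converged
#'   (default 1e-5).
#' @return A `bfs_fit` with estimates (`loadings`, `factor_correlations`,
#'   `residual_variances` on the analyzed metric; `std` fully standardized),
#'   `F_min`, `chi2_naive`, `df`, standard errors and z values, convergence
#'   diagnostics, and (with raw data) `chi2_scaled`, `scaling_factor` and
#'   robust standard errors.
#' @export
fit_ml <- function(spec, data = NULL, sample_cov = NULL, n = NULL,
                   robust = TRUE, start = NULL, max_iter = 500,
                   grad_tol = 1e-5) {
  stopifnot(inherits(spec, "bfs_model"))
  if (is.null(data) && is.null(sample_cov))
    stop("supply either raw data or a sample covariance matrix")
  if (!is.null(data)) {
    data <- as.matrix(data)
    if (!is.null(colnames(data))) {
      miss <- setdiff(spec$indicators, colnames(data))
      if (length(miss)) stop("data lacks indicators: ",
                             paste(miss, collapse = ", "))
      data <- data[, spec$indicators, drop = FALSE]
    }
    n <- nrow(data)
    mu <- colMeans(data)
    Xc <- sweep(data, 2, mu)
    S_cov <- crossprod(Xc) / n                  # ML (divisor n) covariance
    if (any(diag(S_cov) <= 0)) stop("constant indicator column")
  } else {
    if (is.null(n)) stop("n is required with sample_cov")
    S_cov <- as.matrix(sample_cov)
    if (!is.null(rownames(S_cov)) && all(spec$indicators %in% rownames(S_cov)))
      S_cov <- S_cov[spec$indicators, spec$indicators]
    mu <- rep(0, ncol(S_cov))
    Xc <- NULL
  }
  sds <- sqrt(diag(S_cov))
  # optimize on the correlation metric (well scaled for the default start
  # values); the model is scale invariant, so F_min is unchanged and the
  # solution maps back to the covariance metric by rescaling
  S <- stats::cov2cor(S_cov)
  chS <- tryCatch(chol(S), error = function(e)
    stop("sample covariance matrix is not positive definite"))
  logdetS <- 2 * sum(log(diag(chS)))

  lay <- .cfa_layout(spec)
  if (n <= lay$q) stop("sample size must exceed the free-parameter count")
  if (is.null(start))
    start <- c(rep(0.5, lay$nl), rep(0, lay$nph), rep(0.5, lay$p))
  op <- stats::nlminb(start, .cfa_objective, .cfa_gradient,
                      lay = lay, S = S, logdetS = logdetS,
                      control = list(iter.max = max_iter,
                                     eval.max = 4 * max_iter,
                                     rel.tol = 1e-14))
  grad <- .cfa_gradient(op$par, lay, S, logdetS)
  # polish: restart from the solution when the optimizer stops on a relative
  # criterion before the gradient tolerance is reached
  for (restart in 1:3) {
    if (max(abs(grad)) < grad_tol || op$objective >= 1e9) break
    op2 <- stats::nlminb(op$par, .cfa_objective, .cfa_gradient,
                         lay = lay, S = S, logdetS = logdetS,
                         control = list(iter.max = max_iter,
                                        eval.max = 4 * max_iter,
                                        rel.tol = 1e-15))
    if (op2$objective <= op$objective) op <- op2
    g2 <- .cfa_gradient(op$par, lay, S, logdetS)
    if (max(abs(g2)) >= max(abs(grad)) - 1e-12) { grad <- g2; break }
    grad <- g2
  }
  converged <- is.finite(op$objective) && op$objective < 1e9 &&
    max(abs(grad)) < grad_tol
  m <- .cfa_fix_signs(.cfa_unpack(op$par, lay), lay)
  # rescale the solution to the analyzed covariance metric
  m$L <- m$L * sds
  m$Th <- m$Th * sds^2
  Sig <- .cfa_sigma(m)
  F_min <- max(op$objective, 0)

  dimnames(m$Phi) <- list(spec$factor_labels, spec$factor_labels)
  names(m$Th) <- spec$indicators
  dSig <- diag(Sig)
  std <- list(loadings = m$L / sqrt(dSig),
              factor_correlations = m$Phi,
              residual_variances = m$Th / dSig)

  fit <- structure(list(
    spec = spec, loadings = m$L, factor_correlations = m$Phi,
    residual_variances = m$Th, std = std,
    implied = Sig, F_min = F_min,
    chi2_naive = n * F_min, df = model_df(spec), n = n, npar = lay$q,
    converged = converged, iterations = op$iterations,
    grad_norm = max(abs(grad)),
    sample = list(S = S_cov, means = mu, sds = sds, n = n),
    se_naive = NULL, se_robust = NULL, z = NULL,
    chi2_scaled = NULL, scaling_factor = NULL,
    baseline_scaling_factor = NULL
  ), class = "bfs_fit")

  if (converged) {
    fit <- .cfa_naive_se(fit, lay)
    if (robust && !is.null(Xc))
      fit <- robust_corrections(Xc, spec, fit)
  }
  fit$admissibility <- check_admissibility(fit)
  fit
}

# naive (normal-theory) standard errors: acov = (1/n) (Delta' W Delta)^-1
.cfa_naive_se <- function(fit, lay = NULL) {
  if (is.null(lay)) lay <- .cfa_layout(fit$spec)
  m <- list(L = fit$loadings, Phi = fit$factor_correlations,
            Th = fit$residual_variances)
  iSig <- tryCatch(solve(fit$implied), error = function(e) NULL)
  if (is.null(iSig)) return(fit)
  Delta <- .cfa_delta(m, lay)
  W <- .cfa_weight(iSig)
  A <- t(Delta) %*% W %*% Delta
  acov <- tryCatch(solve(A) / fit$n, error = function(e) NULL)
  if (is.null(acov)) return(fit)
  se <- sqrt(pmax(diag(acov), 0))
  fit$se_naive <- .cfa_se_list(se, lay)
  fit$.delta <- Delta
  fit$.weight <- W
  fit$.info <- A
  fit$z <- .cfa_z(fit, fit$se_naive)
  fit
}

.cfa_se_list <- function(se, lay) {
  L <- matrix(NA_real_, lay$p, lay$k, dimnames = dimnames(lay$pat))
  L[lay$pat] <- se[seq_len(lay$nl)]
  phi <- if (lay$nph) se[lay$nl + seq_len(lay$nph)] else numeric()
  list(loadings = L, factor_correlations = phi,
       residual_variances = se[lay$nl + lay$nph + seq_len(lay$p)])
}

.cfa_z <- function(fit, se) {
  lam <- fit$loadings[fit$spec$loading_pattern]
  s <- se$loadings[fit$spec$loading_pattern]
  z <- lam / s
  names(z) <- paste(rownames(fit$loadings)[which(fit$spec$loading_pattern,
                                                 arr.ind = TRUE)[, 1]],
                    colnames(fit$loadings)[which(fit$spec$loading_pattern,
                                                 arr.ind = TRUE)[, 2]],
                    sep = "~")
  z
}

#' Satorra-Bentler corrections from raw data
#'
#' Computes the asymptotic covariance of the sample moments (the ADF
#' fourth-moment matrix Gamma) from the raw data and derives the
#' Satorra-Bentler mean-scaled chi-square
#' \eqn{T_{SB} = T / c}, \eqn{c = tr(U\Gamma)/df} with
#' \eqn{U = W - W\Delta(\Delta'W\Delta)^{-1}\Delta'W},
#' sandwich standard errors
#' \eqn{n^{-1} A^{-1} (\Delta'W\Gamma W\Delta) A^{-1}}, and the scaling
#' factor of the independence baseline (needed for robust CFI/TLI).
#'
#' @param raw_data n x 11 matrix on the scale the model was fitted to
#'   (standardized internally if the fit analyzed correlations).
#' @param spec The `bfs_model` that was fitted.
#' @param fit The `bfs_fit` to update.
#' @return The fit with `chi2_scaled`, `scaling_factor`,
#'   `baseline_scaling_factor`, `se_robust` and robust `z` filled in. If the
#'   model Jacobian is rank deficient the naive values are retained and a
#'   warning is issued.
#' @export
robust_corrections <- function(raw_data, spec, fit) {
  stopifnot(inherits(fit, "bfs_fit"))
  if (!isTRUE(fit$converged)) return(fit)
  X <- as.matrix(raw_data)
  if (!is.null(colnames(X))) X <- X[, spec$indicators, drop = FALSE]
  Gamma <- .gamma_adf(X)

  lay <- .cfa_layout(spec)
  if (is.null(fit$.delta)) fit <- .cfa_naive_se(fit, lay)
  Delta <- fit$.delta; W <- fit$.weight; A <- fit$.info
  Ainv <- tryCatch(solve(A), error = function(e) NULL)
  if (is.null(Ainv) || is.null(Delta)) {
    warning("rank-deficient Jacobian: robust corrections unavailable, ",
            "naive statistics retained")
    return(fit)
  }
  U <- W - W %*% Delta %*% Ainv %*% t(Delta) %*% W
  cfac <- sum(U * t(Gamma)) / fit$df
  if (is.finite(cfac) && cfac > 0) {
    fit$scaling_factor <- cfac
    fit$chi2_scaled <- fit$chi2_naive / cfac
  } else {
    warning("non-positive scaling factor: naive statistics retained")
  }
  B <- t(Delta) %*% W %*% Gamma %*% W %*% Delta
  acov <- Ainv %*% B %*% Ainv / fit$n
  fit$se_robust <- .cfa_se_list(sqrt(pmax(diag(acov), 0)), lay)
  fit$z <- .cfa_z(fit, fit$se_robust)

  # scaled statistic for the independence baseline (free variances only):
  # Delta_b columns are vech(E_ii)
  p <- lay$p
  # the baseline (independence) model's implied covariance is diag(S)
  iD <- diag(1 / diag(fit$sample$S), p)
  Wb <- .cfa_weight(iD)
  low <- lower.tri(diag(p), diag = TRUE)
  Db <- vapply(seq_len(p), function(i) {
    M <- matrix(0, p, p); M[i, i] <- 1; M[low]
  }, numeric(p * (p + 1) / 2))
  Ab <- t(Db) %*% Wb %*% Db
  Ub <- Wb - Wb %*% Db %*% solve(Ab) %*% t(Db) %*% Wb
  dfb <- p * (p - 1) / 2
  cb <- sum(Ub * t(Gamma)) / dfb
  if (is.finite(cb) && cb > 0) fit$baseline_scaling_factor <- cb
  fit$admissibility <- check_admissibility(fit)
  fit
}

#' Admissibility diagnostics for a fitted model
#'
#' Applies the admissibility screen used for "model utility": the solution
#' must have converged, every free loading significant (two-sided test on the
#' robust z when available), no negative standardized loadings (after the
#' canonical sign convention), no negative residual variances (Heywood
#' cases), and no non-positive-definite implied or latent covariance matrix
#' (eigenvalue threshold -1e-8).
#'
#' @param fit A `bfs_fit`.
#' @param alpha Two-sided significance level for the loading test
#'   (default .05).
#' @return A `bfs_admissibility` list of logical flags with
#'   `overall_admissible` the conjunction, plus the loading p-values.
#' @export
check_admissibility <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "bfs_fit"))
  conv <- isTRUE(fit$converged)
  pvals <- rep(NA_real_, sum(fit$spec$loading_pattern))
  sig <- FALSE
  if (conv && !is.null(fit$z)) {
    pvals <- 2 * stats::pnorm(-abs(fit$z))
    sig <- all(is.finite(pvals)) && all(pvals < alpha)
  }
  tol <- -1e-8
  no_neg_load <- conv &&
    all(fit$std$loadings[fit$spec$loading_pattern] >= tol)
  no_neg_var <- conv && all(fit$residual_variances >= tol)
  npd_ok <- FALSE
  if (conv) {
    ev_phi <- eigen(fit$factor_correlations, symmetric = TRUE,
                    only.values = TRUE)$values
    ev_sig <- eigen(fit$implied, symmetric = TRUE, only.values = TRUE)$values
    npd_ok <- min(ev_phi) > tol && min(ev_sig) > tol &&
      max(abs(fit$factor_correlations)) <= 1 + 1e-8
  }
  structure(list(converged = conv,
                 all_loadings_significant = isTRUE(sig),
                 no_negative_loadings = isTRUE(no_neg_load),
                 no_negative_variances = isTRUE(no_neg_var),
                 no_npd_issues = isTRUE(npd_ok),
                 overall_admissible = conv && isTRUE(sig) &&
                   isTRUE(no_neg_load) && isTRUE(no_neg_var) &&
                   isTRUE(npd_ok),
                 loading_p_values = pvals,
                 alpha = alpha),
            class = "bfs_admissibility")
}

#' @export
print.bfs_fit <- function(x, ...) {
  cat("<bfs_fit>", x$spec$model_id,
      sprintf("| n = %d, df = %d", x$n, x$df), "\n")
  cat(sprintf("  F_min = %.6f, chi2 = %.2f", x$F_min, x$chi2_naive))
  if (!is.null(x$chi2_scaled))
    cat(sprintf(" (scaled %.2f, c = %.3f)", x$chi2_scaled,
                x$scaling_factor))
  cat("\n  converged:", x$converged,
      "| admissible:", isTRUE(x$admissibility$overall_admissible), "\n")
  invisible(x)
}
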