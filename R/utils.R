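# half-vectorization (column-major lower triangle, diagonal included)
.vech <- function(M) M[lower.tri(M, diag = TRUE)]

# duplication matrix D: vec(M) = D %*% vech(M) for symmetric M
.duplication <- function(p) {
  D <- matrix(0, p * p, p * (p + 1) / 2)
  k <- 0
  for (j in seq_len(p)) for (i in j:p) {
    k <- k + 1
    D[(j - 1) * p + i, k] <- 1
    D[(i - 1) * p + j, k] <- 1
  }
  D
}

# asymptotic covariance of vech(S) estimated from raw (already centered or
# not) data: the ADF fourth-moment estimator
.gamma_adf <- function(X) {
  X <- sweep(as.matrix(X), 2, colMeans(X))
  n <- nrow(X); p <- ncol(X)
  idx <- which(lower.tri(diag(p), diag = TRUE), arr.ind = TRUE)
  Z <- X[, idx[, 1], drop = FALSE] * X[, idx[, 2], drop = FALSE]
  Z <- sweep(Z, 2, colMeans(Z))
  crossprod(Z) / n
}
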