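#' Fleishman power-method coefficients
#'
#' Solves for the coefficients of the cubic polynomial transform
#' \eqn{Y = a + bZ + cZ^2 + dZ^3} (with \eqn{a = -c}, \eqn{Z} standard
#' normal) such that \eqn{Y} has mean 0, variance 1 and the requested
#' skewness and excess kurtosis. The three moment equations are solved by
#' Newton iteration with an analytic Jacobian.
#'
#' @param skew Target skewness (third standardized moment).
#' @param excess_kurtosis Target excess kurtosis (fourth standardized moment
#'   minus 3). Must satisfy `excess_kurtosis >= skew^2 - 2` and lie inside
#'   the polynomial-solvable region, otherwise an error is thrown.
#' @return Named numeric vector `c(a, b, c, d)`.
#' @examples
#' fleishman_coefficients(0, 0)  # identity: (0, 1, 0, 0)
#' @export
fleishman_coefficients <- function(skew, excess_kurtosis) {
  stopifnot(is.finite(skew), is.finite(excess_kurtosis))
  if (excess_kurtosis < skew^2 - 2)
    stop("infeasible moment pair: excess kurtosis must be >= skew^2 - 2")
  if (skew == 0 && excess_kurtosis == 0)
    return(c(a = 0, b = 1, c = 0, d = 0))
  f <- function(x) {
    b <- x[1]; cc <- x[2]; d <- x[3]
    c(b^2 + 6 * b * d + 2 * cc^2 + 15 * d^2 - 1,
      2 * cc * (b^2 + 24 * b * d + 105 * d^2 + 2) - skew,
      24 * (b * d + cc^2 * (1 + b^2 + 28 * b * d) +
              d^2 * (12 + 48 * b * d + 141 * cc^2 + 225 * d^2)) -
        excess_kurtosis)
  }
  jac <- function(x) {
    b <- x[1]; cc <- x[2]; d <- x[3]
    rbind(
      c(2 * b + 6 * d, 4 * cc, 6 * b + 30 * d),
      c(2 * cc * (2 * b + 24 * d),
        2 * (b^2 + 24 * b * d + 105 * d^2 + 2),
        2 * cc * (24 * b + 210 * d)),
      c(24 * (d + cc^2 * (2 * b + 28 * d) + 48 * d^3),
        48 * cc * (1 + b^2 + 28 * b * d) + 24 * 282 * d^2 * cc,
        24 * (b + 28 * b * cc^2 + 2 * d * (12 + 48 * b * d + 141 * cc^2 +
                                             225 * d^2) +
                d^2 * (48 * b + 450 * d)))
    )
  }
  # start near the normal identity; nudge c toward the requested skew
  x <- c(b = 1, cc = skew / 6, d = 0)
  ok <- FALSE
  for (i in 1:200) {
    fx <- f(x)
    if (max(abs(fx)) < 1e-12) { ok <- TRUE; break }
    step <- tryCatch(solve(jac(x), -fx), error = function(e) NULL)
    if (is.null(step)) break
    # damped Newton: halve the step until the residual stops growing
    lam <- 1
    repeat {
      xn <- x + lam * step
      if (max(abs(f(xn))) < max(abs(fx)) + 1e-12 || lam < 1e-3) break
      lam <- lam / 2
    }
    x <- xn
  }
  if (!ok && max(abs(f(x))) > 1e-8)
    stop("Fleishman system did not converge: moment pair (",
         skew, ", ", excess_kurtosis, ") outside the solvable region")
  c(a = -unname(x[2]), b = unname(x[1]), c = unname(x[2]), d = unname(x[3]))
}

#' Apply a Fleishman polynomial transform
#'
#' @param z Numeric vector of standard-normal variates.
#' @param coef Coefficients from [fleishman_coefficients()].
#' @return Transformed vector with the coefficients' target moments.
#' @export
fleishman_transform <- function(z, coef) {
  coef[["a"]] + coef[["b"]] * z + coef[["c"]] * z^2 + coef[["d"]] * z^3
}

#' Vale-Maurelli intermediate correlation
#'
#' Post-transform correlation between two Fleishman variates is a cubic in
#' the pre-transform (intermediate) normal correlation \eqn{\rho}:
#' \deqn{r = \rho(b_i b_j + 3 b_i d_j + 3 d_i b_j + 9 d_i d_j)
#'          + 2 \rho^2 c_i c_j + 6 \rho^3 d_i d_j.}
#' This solves that cubic for \eqn{\rho} so that, after transformation, the
#' sample correlation converges to `target_r`.
#'
#' @param target_r Desired post-transform correlation, in `[-1, 1]`.
#' @param coef_i,coef_j Fleishman coefficient vectors of the two margins.
#' @return The intermediate correlation, a scalar in `[-1, 1]`.
#' @export
intermediate_correlation <- function(target_r, coef_i, coef_j) {
  stopifnot(abs(target_r) <= 1)
  b1 <- coef_i[["b"]]; c1 <- coef_i[["c"]]; d1 <- coef_i[["d"]]
  b2 <- coef_j[["b"]]; c2 <- coef_j[["c"]]; d2 <- coef_j[["d"]]
  k1 <- b1 * b2 + 3 * b1 * d2 + 3 * d1 * b2 + 9 * d1 * d2
  k2 <- 2 * c1 * c2
  k3 <- 6 * d1 * d2
  if (target_r == 0 && k2 == 0) return(0)
  coefs <- c(-target_r, k1, k2, k3)
  while (length(coefs) > 2 && coefs[length(coefs)] == 0)
    coefs <- coefs[-length(coefs)]
  roots <- polyroot(coefs)
  real <- Re(roots[abs(Im(roots)) < 1e-8])
  real <- real[real >= -1 - 1e-10 & real <= 1 + 1e-10]
  if (!length(real))
    stop("no intermediate correlation in [-1, 1] reproduces target ",
         target_r)
  # the physically meaningful root is the one nearest the target
  rho <- real[which.min(abs(real - target_r))]
  min(1, max(-1, rho))
}
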