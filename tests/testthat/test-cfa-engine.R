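test_that("fitting a model to its own implied moments recovers the truth", {
  spec <- build_model("C_revised_bifactor")
  par <- generating_parameters("caspi")
  S <- implied_covariance(spec, par)
  fit <- fit_ml(spec, sample_cov = S, n = 100000)
  expect_true(fit$converged)
  expect_lt(fit$F_min, 1e-10)
  expect_equal(unname(fit$loadings), unname(par$loadings), tolerance = 1e-5)
  expect_equal(fit$factor_correlations["Ext", "Int"], -0.471,
               tolerance = 1e-5)
  expect_equal(unname(fit$residual_variances),
               unname(par$residual_variances), tolerance = 1e-5)
  expect_true(fit$admissibility$overall_admissible)
})

test_that("three-indicator fits match the closed-form solution", {
  # just-identified single factor: lambda_1 = sqrt(s12 s13 / s23), cyclically
  set.seed(42)
  for (rep in 1:5) {
    lam <- runif(3, 0.4, 0.9)
    S <- toy_sigma(lam)
    fit <- fit_ml(single_factor_toy(3), sample_cov = S, n = 1000)
    s12 <- S[1, 2]; s13 <- S[1, 3]; s23 <- S[2, 3]
    closed <- c(sqrt(s12 * s13 / s23), sqrt(s12 * s23 / s13),
                sqrt(s13 * s23 / s12))
    expect_equal(unname(fit$loadings[, 1]), closed, tolerance = 1e-6)
    expect_lt(fit$F_min, 1e-9)  # saturated: F = 0 iff Sigma(theta) = S
  }
})

test_that("single-factor estimates agree with factanal", {
  set.seed(8)
  n <- 800
  lam <- c(.75, .6, .8, .55, .7, .65)
  eta <- rnorm(n)
  X <- sapply(lam, function(l) l * eta + rnorm(n, sd = sqrt(1 - l^2)))
  colnames(X) <- paste0("y", 1:6)
  fit <- fit_ml(single_factor_toy(6), data = X, robust = FALSE)
  fa <- factanal(covmat = cor(X), factors = 1, n.obs = n)
  expect_equal(unname(fit$std$loadings[, 1]),
               unname(as.vector(fa$loadings)), tolerance = 2e-3)
})

test_that("the optimizer matches a brute-force search on random instances", {
  set.seed(77)
  for (rep in 1:20) {
    p <- sample(3:5, 1)
    lam <- runif(p, 0.3, 0.9)
    # perturbed sample-like matrix, kept positive definite
    E <- matrix(rnorm(p * p, sd = 0.03), p, p)
    S <- toy_sigma(lam) + (E + t(E)) / 2
    diag(S) <- 1
    if (min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) < 0.05)
      next
    spec <- single_factor_toy(p)
    fit <- fit_ml(spec, sample_cov = S, n = 500)
    # grid + polish: Nelder-Mead from several random starts
    obj <- function(th) {
      L <- matrix(th[1:p], p, 1)
      Sig <- L %*% t(L) + diag(th[p + 1:p], p)
      ch <- tryCatch(chol(Sig), error = function(e) NULL)
      if (is.null(ch)) return(1e10)
      2 * sum(log(diag(ch))) + sum(chol2inv(ch) * S) -
        determinant(S)$modulus[1] - p
    }
    best <- Inf
    for (s in 1:8) {
      st <- c(runif(p, 0.2, 0.9), runif(p, 0.2, 0.9))
      o <- optim(st, obj, method = "Nelder-Mead",
                 control = list(maxit = 5000, reltol = 1e-12))
      o <- optim(o$par, obj, method = "BFGS",
                 control = list(reltol = 1e-14))
      best <- min(best, o$value)
    }
    expect_equal(fit$F_min, as.numeric(best), tolerance = 1e-4)
  }
})

test_that("factor sign indeterminacy is resolved canonically", {
  spec <- single_factor_toy(4)
  S <- toy_sigma(c(.7, .6, .8, .5))
  flipped_start <- c(rep(-0.5, 4), rep(0.5, 4))
  f1 <- fit_ml(spec, sample_cov = S, n = 500)
  f2 <- fit_ml(spec, sample_cov = S, n = 500, start = flipped_start)
  expect_equal(f1$loadings, f2$loadings, tolerance = 1e-5)
  expect_true(all(colSums(f1$loadings) >= 0))
})

test_that("scaling factor is near 1 for normal data, above 1 for skewed", {
  spec <- single_factor_toy(4)
  lam <- c(.7, .6, .8, .5)
  set.seed(13)
  n <- 20000
  eta <- rnorm(n)
  X <- sapply(lam, function(l) l * eta + rnorm(n, sd = sqrt(1 - l^2)))
  colnames(X) <- paste0("y", 1:4)
  fit <- fit_ml(spec, data = X)
  expect_true(fit$converged)
  expect_equal(fit$scaling_factor, 1, tolerance = 0.1)
  expect_equal(fit$chi2_scaled, fit$chi2_naive,
               tolerance = 0.15 * max(fit$chi2_naive, 1))

  # leptokurtic data inflate the naive statistic: c > 1, across seeds
  for (s in 1:3) {
    Xs <- skewed_factor_data(20000, lam, seed = s)
    fs <- fit_ml(single_factor_toy(4), data = Xs)
    expect_true(fs$converged)
    expect_gt(fs$scaling_factor, 1.05)
  }
})

test_that("robust standard errors track the sampling distribution", {
  # Monte-Carlo: empirical SD of the first loading vs mean reported SE
  lam <- c(.7, .6, .8, .5)
  ests <- ses <- numeric(120)
  for (i in seq_along(ests)) {
    X <- skewed_factor_data(400, lam, seed = 1000 + i)
    f <- fit_ml(single_factor_toy(4), data = X)
    ests[i] <- f$loadings[1, 1]
    ses[i] <- f$se_robust$loadings[1, 1]
  }
  expect_lt(abs(mean(ses) - sd(ests)), 0.25 * sd(ests))
})

test_that("the ADF fourth-moment matrix agrees with a bootstrap estimate", {
  set.seed(5)
  X <- skewed_factor_data(400, c(.7, .6, .8), seed = 5)
  G <- bifactorsim:::.gamma_adf(X)
  B <- 300
  n <- nrow(X)
  vechs <- replicate(B, {
    idx <- sample(n, replace = TRUE)
    Xi <- X[idx, , drop = FALSE]
    Xi <- sweep(Xi, 2, colMeans(Xi))
    bifactorsim:::.vech(crossprod(Xi) / n)
  })
  Gb <- n * cov(t(vechs))
  # bootstrap covariances are noisy; require agreement in scale and pattern
  expect_equal(unname(diag(Gb)), unname(diag(G)),
               tolerance = 0.4 * max(diag(G)))
  expect_gt(cor(bifactorsim:::.vech(G), bifactorsim:::.vech(Gb)), 0.95)
})

test_that("admissibility flags fire on the classic failure modes", {
  # Heywood case: r12 = r13 = .7, r23 = .3 forces lambda_1^2 = 49/30 > 1,
  # hence a negative residual variance, from a positive-definite input
  S <- matrix(c(1, .7, .7, .7, 1, .3, .7, .3, 1), 3, 3)
  fit <- fit_ml(single_factor_toy(3), sample_cov = S, n = 500)
  expect_true(fit$converged)
  expect_false(fit$admissibility$no_negative_variances)
  expect_false(fit$admissibility$overall_admissible)

  # weak loading at modest n: not significant at alpha = .05
  set.seed(3)
  n <- 150
  eta <- rnorm(n)
  lam <- c(.8, .7, .6, .05)
  X <- sapply(lam, function(l) l * eta + rnorm(n, sd = sqrt(1 - l^2)))
  colnames(X) <- paste0("y", 1:4)
  f2 <- fit_ml(single_factor_toy(4), data = X)
  adm <- check_admissibility(f2, alpha = 0.05)
  expect_false(adm$all_loadings_significant)

  # a clean fit passes every flag
  S3 <- toy_sigma(c(.7, .6, .8, .5))
  f3 <- fit_ml(single_factor_toy(4), sample_cov = S3, n = 2000)
  expect_true(f3$admissibility$overall_admissible)
})

test_that("non-positive-definite input is rejected", {
  S <- matrix(c(1, 1.2, 1.2, 1), 2, 2)
  expect_error(fit_ml(single_factor_toy(2), sample_cov = S, n = 100),
               "positive definite")
})
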