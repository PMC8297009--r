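test_that("marginal skewness follows the population g1 convention", {
  expect_equal(marginal_skewness(c(-1, 0, 1)), 0)
  set.seed(7)
  x <- rexp(1e6)  # analytic skewness of the exponential is 2
  expect_equal(marginal_skewness(x), 2, tolerance = 0.05)
  expect_error(marginal_skewness(rep(1, 10)), "constant")
  expect_error(marginal_skewness(c(1, 2)), "3 values")
})

test_that("generation is bit-reproducible under a fixed seed", {
  cfg <- simulation_config(n_subjects = 500, seed = 123)
  p1 <- generate_population(cfg)
  p2 <- generate_population(cfg)
  expect_identical(p1$symptoms, p2$symptoms)
  expect_identical(p1$covariates, p2$covariates)
  expect_identical(p1$latent_scores, p2$latent_scores)
})

test_that("generated symptoms match the implied correlation structure", {
  cfg <- simulation_config(n_subjects = 100000, seed = 31)
  pop <- generate_population(cfg)
  implied <- implied_covariance(cfg$model, cfg$generating_params)
  err <- max(abs(cor(pop$symptoms) - implied))
  expect_lt(err, 0.02)
  skews <- apply(pop$symptoms, 2, marginal_skewness)
  expect_equal(mean(skews), 2, tolerance = 0.1)
})

test_that("zero skew targets reduce to multivariate normal generation", {
  cfg <- simulation_config(n_subjects = 100000, target_skew = 0,
                           target_excess_kurtosis = 0, seed = 5)
  pop <- generate_population(cfg)
  skews <- apply(pop$symptoms, 2, marginal_skewness)
  expect_true(all(abs(skews) < 0.05))
  implied <- implied_covariance(cfg$model, cfg$generating_params)
  expect_lt(max(abs(cor(pop$symptoms) - implied)), 0.02)
})

test_that("disabling the intermediate-correlation solve attenuates structure", {
  raw <- generate_population(simulation_config(
    n_subjects = 50000, seed = 11, vale_maurelli = FALSE))
  corrected <- generate_population(simulation_config(
    n_subjects = 50000, seed = 11, vale_maurelli = TRUE))
  implied <- implied_covariance(build_model("C_revised_bifactor"),
                                generating_parameters("caspi"))
  off <- lower.tri(implied)
  # naive mode shrinks correlations toward zero relative to the target
  expect_lt(mean(abs(cor(raw$symptoms)[off])),
            mean(abs(implied[off])))
  expect_lt(mean(abs(cor(raw$symptoms)[off])),
            mean(abs(cor(corrected$symptoms)[off])))
})

test_that("covariates hit their target factor correlations", {
  cfg <- simulation_config(n_subjects = 100000, seed = 17)
  pop <- generate_population(cfg)
  expect_equal(unname(colMeans(pop$covariates)), rep(100, 4),
               tolerance = 0.5)
  expect_equal(unname(apply(pop$covariates, 2, sd)), rep(15, 4),
               tolerance = 0.5)
  tg <- covariate_targets("caspi")
  r <- cor(pop$covariates, pop$latent_scores)[, colnames(tg)]
  expect_lt(max(abs(r - tg)), 0.01)
  # covariate marginals are normal-looking
  expect_true(all(abs(apply(pop$covariates, 2, marginal_skewness)) < 0.05))
})

test_that("covariate weights agree with a least-squares oracle", {
  phi <- generating_parameters("caspi")$factor_correlations
  r <- covariate_targets("caspi")["WM", ]
  w <- solve(phi, r)
  # brute-force: minimize || phi w - r ||^2 numerically
  w2 <- optim(c(0, 0, 0), function(w) sum((phi %*% w - r)^2),
              method = "BFGS", control = list(reltol = 1e-14))$par
  expect_equal(unname(w), unname(w2), tolerance = 1e-5)
})

test_that("degenerate covariate targets are handled", {
  set.seed(2)
  eta <- matrix(rnorm(3000), 1000, 3,
                dimnames = list(NULL, c("p", "Ext", "Int")))
  tg <- matrix(0, 1, 3, dimnames = list("noise", c("p", "Ext", "Int")))
  y <- generate_covariates(eta, tg, phi = diag(3))
  expect_true(all(abs(cor(y, eta)) < 0.1))
  tg2 <- matrix(c(.8, .8, .8), 1, 3,
                dimnames = list("bad", c("p", "Ext", "Int")))
  expect_error(generate_covariates(eta, tg2, phi = diag(3)), "R-squared")
})

test_that("per-variable skew jitter stays feasible and near its centre", {
  cfg <- simulation_config(n_subjects = 20000, seed = 9, jitter_skew = TRUE)
  pop <- generate_population(cfg)
  skews <- apply(pop$symptoms, 2, marginal_skewness)
  expect_gt(sd(skews), 0.03)        # jitter actually varies the margins
  expect_equal(mean(skews), 2, tolerance = 0.4)
})

test_that("population CSV round-trips with its JSON sidecar", {
  pop <- quick_population(n = 200, seed = 3)
  f <- file.path(tempdir(), "pop.csv")
  write_population(pop, f)
  df <- read_population(f)
  expect_equal(nrow(df), 200)
  expect_true(all(psycho_indicators() %in% names(df)))
  expect_equal(df$alc, unname(pop$symptoms[, "alc"]), tolerance = 1e-6)
  meta <- jsonlite::read_json(sub("csv$", "json", f))
  expect_equal(meta$n_subjects, 200)
  expect_equal(meta$seed, 3)
  unlink(c(f, sub("csv$", "json", f)))
})
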