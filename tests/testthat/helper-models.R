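# toy model templates for oracle tests: a bfs_model with an arbitrary
# indicator count / pattern, sharing the production engine's layout
toy_model <- function(pattern, free_pairs = matrix(character(), 0, 2),
                      factor_labels = colnames(pattern),
                      indicators = rownames(pattern)) {
  if (is.null(indicators)) {
    indicators <- paste0("y", seq_len(nrow(pattern)))
    rownames(pattern) <- indicators
  }
  if (is.null(factor_labels)) {
    factor_labels <- paste0("f", seq_len(ncol(pattern)))
    colnames(pattern) <- factor_labels
  }
  structure(list(model_id = "toy", indicators = indicators,
                 factor_labels = factor_labels, loading_pattern = pattern,
                 free_factor_correlations = free_pairs,
                 fixed_orthogonal = matrix(character(), 0, 2)),
            class = "bfs_model")
}

single_factor_toy <- function(p) {
  toy_model(matrix(TRUE, p, 1, dimnames = list(paste0("y", 1:p), "f1")))
}

# implied covariance of a 1-factor model on the standardized metric
toy_sigma <- function(lambda) {
  S <- outer(lambda, lambda)
  diag(S) <- 1
  S
}

# small skewed single-factor dataset for robust-statistics tests
skewed_factor_data <- function(n, lambda = c(.7, .6, .8, .5), seed = 1) {
  set.seed(seed)
  eta <- rnorm(n)
  p <- length(lambda)
  X <- sapply(seq_len(p), function(i) {
    e <- rnorm(n, sd = sqrt(1 - lambda[i]^2))
    y <- lambda[i] * eta + e
    co <- fleishman_coefficients(1.5, 4)
    fleishman_transform(y, co)  # y ~ N(0,1) marginally, transform keeps scale
  })
  colnames(X) <- paste0("y", 1:p)
  X
}

quick_population <- function(n = 5000, seed = 1, ...) {
  generate_population(simulation_config(n_subjects = n, seed = seed, ...))
}
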