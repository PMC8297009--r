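#' Simulation configuration
#'
#' Bundles everything needed to generate a reproducible synthetic population:
#' sample size, per-variable skew/kurtosis targets, the generating model and
#' parameters, the covariate targets, and the RNG seed. Defaults reproduce the
#' study conditions: 100,000 subjects, all marginal skews 2.0, generation from
#' the published Dunedin-cohort revised bifactor solution, and IQ covariates
#' matched to its factor correlations.
#'
#' @param n_subjects Number of subjects (default 100,000).
#' @param target_skew Scalar or length-11 vector of marginal skew targets.
#' @param target_excess_kurtosis Scalar or length-11 vector of excess-kurtosis
#'   targets (default 7, comfortably inside the Fleishman region for skew 2
#'   and resembling count-like symptom data).
#' @param generating_params `bfs_params` for the generating model (default
#'   [generating_parameters()] `"caspi"` revised bifactor).
#' @param model The generating `bfs_model` (default revised bifactor).
#' @param vale_maurelli Apply the intermediate-correlation correction so the
#'   post-transform correlations match the implied covariance (default TRUE).
#'   With `FALSE` ("naive" mode) the transform is applied to normals drawn at
#'   the target correlations and the realized correlations are attenuated.
#' @param jitter_skew If TRUE, per-variable skew targets are drawn once from
#'   N(mean(target_skew), jitter_sd^2), truncated to the feasible region.
#' @param jitter_sd SD of the skew jitter (default .35).
#' @param covariate_targets 4 x 3 matrix of covariate-factor correlation
#'   targets (default [covariate_targets()] `"caspi"`), or NULL to skip
#'   covariate generation.
#' @param covariate_mean,covariate_sd Covariate scale (default 100 / 15).
#' @param seed Integer RNG seed, or NULL.
#' @return A `bfs_sim_config` list.
#' @export
simulation_config <- function(n_subjects = 100000,
                              target_skew = 2,
                              target_excess_kurtosis = 7,
                              generating_params = generating_parameters("caspi"),
                              model = build_model("C_revised_bifactor"),
                              vale_maurelli = TRUE,
                              jitter_skew = FALSE,
                              jitter_sd = 0.35,
                              covariate_targets = bifactorsim::covariate_targets("caspi"),
                              covariate_mean = 100,
                              covariate_sd = 15,
                              seed = NULL) {
  stopifnot(n_subjects >= 2)
  p <- length(model$indicators)
  target_skew <- rep_len(target_skew, p)
  target_excess_kurtosis <- rep_len(target_excess_kurtosis, p)
  if (any(target_excess_kurtosis < target_skew^2 - 2))
    stop("some (skew, kurtosis) targets fall outside the feasible region")
  structure(list(n_subjects = as.integer(n_subjects),
                 target_skew = target_skew,
                 target_excess_kurtosis = target_excess_kurtosis,
                 generating_params = generating_params,
                 model = model,
                 vale_maurelli = isTRUE(vale_maurelli),
                 jitter_skew = isTRUE(jitter_skew),
                 jitter_sd = jitter_sd,
                 covariate_targets = covariate_targets,
                 covariate_mean = covariate_mean,
                 covariate_sd = covariate_sd,
                 seed = seed),
            class = "bfs_sim_config")
}

#' Marginal skewness
#'
#' Population (biased) skewness estimator
#' \eqn{g_1 = m_3 / m_2^{3/2}} on central moments with divisor n.
#'
#' @param values Numeric vector, length >= 3, non-constant.
#' @return Scalar skewness.
#' @export
marginal_skewness <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 3) stop("need at least 3 values")
  m <- mean(values)
  m2 <- mean((values - m)^2)
  if (m2 <= 0) stop("skewness undefined for a constant vector")
  mean((values - m)^3) / m2^1.5
}

# smallest symmetric PSD repair: clip eigenvalues from below
.clip_psd <- function(M, eps = 1e-10) {
  M <- (M + t(M)) / 2
  e <- eigen(M, symmetric = TRUE)
  if (min(e$values) >= eps) return(M)
  M2 <- e$vectors %*% (pmax(e$values, eps) * t(e$vectors))
  (M2 + t(M2)) / 2
}

# draw n x p standard-normal rows with covariance C (eigen factor, stable
# for matrices repaired to the PSD boundary)
.rmvn <- function(n, C) {
  e <- eigen(C, symmetric = TRUE)
  fac <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(C))
  matrix(stats::rnorm(n * nrow(C)), n) %*% t(fac)
}

#' Generate the synthetic population
#'
#' Draws latent factor scores and symptom variables jointly from the
#' generating model's implied structure, induces the target marginal skews
#' with Fleishman polynomial transforms (by default with Vale-Maurelli
#' intermediate correlations so the post-transform correlation matrix matches
#' the model-implied one), and builds the four IQ covariates from the true
#' latent draws with the configured target correlations.
#'
#' @param config A `bfs_sim_config` from [simulation_config()].
#' @return A `bfs_population`: list with `symptoms` (n x 11 matrix),
#'   `covariates` (n x 4 matrix or NULL), `latent_scores` (n x k matrix of
#'   generating factor draws), `fleishman` (per-variable coefficients),
#'   `config`.
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "bfs_sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  spec <- config$model
  params <- config$generating_params
  n <- config$n_subjects
  p <- length(spec$indicators)
  k <- length(spec$factor_labels)

  skews <- config$target_skew
  if (config$jitter_skew) {
    skews <- stats::rnorm(p, mean(config$target_skew), config$jitter_sd)
    # truncate to the (approximate) power-method feasible region:
    # excess kurtosis >= -1.2264 + 1.6410 * skew^2, with a small margin
    lim <- 0.98 * sqrt(pmax(
      (config$target_excess_kurtosis + 1.2264) / 1.6410, 0))
    skews <- pmin(pmax(skews, -lim), lim)
  }
  coefs <- lapply(seq_len(p), function(i)
    fleishman_coefficients(skews[i], config$target_excess_kurtosis[i]))

  Sigma <- implied_covariance(spec, params)
  Rstar <- Sigma
  if (config$vale_maurelli) {
    for (i in seq_len(p - 1)) for (j in (i + 1):p) {
      Rstar[i, j] <- Rstar[j, i] <-
        intermediate_correlation(Sigma[i, j], coefs[[i]], coefs[[j]])
    }
  }
  Phi <- params$factor_correlations
  cross <- params$loadings %*% Phi      # cov(symptom normals, factors)
  joint <- rbind(cbind(Phi, t(cross)),
                 cbind(cross, Rstar))
  joint <- .clip_psd(joint)
  draws <- .rmvn(n, joint)
  latent <- draws[, seq_len(k), drop = FALSE]
  colnames(latent) <- spec$factor_labels
  z <- draws[, k + seq_len(p), drop = FALSE]
  symptoms <- vapply(seq_len(p), function(i)
    fleishman_transform(z[, i], coefs[[i]]), numeric(n))
  colnames(symptoms) <- spec$indicators

  covariates <- NULL
  if (!is.null(config$covariate_targets)) {
    covariates <- generate_covariates(latent, config$covariate_targets,
                                      phi = Phi,
                                      mean = config$covariate_mean,
                                      sd = config$covariate_sd)
  }
  structure(list(symptoms = symptoms, covariates = covariates,
                 latent_scores = latent,
                 fleishman = coefs, config = config),
            class = "bfs_population")
}

#' @export
print.bfs_population <- function(x, ...) {
  cat("<bfs_population> n =", nrow(x$symptoms),
      "| mean marginal skew =",
      round(mean(apply(x$symptoms, 2, marginal_skewness)), 3), "\n")
  invisible(x)
}

#' Generate the symptom matrix only
#'
#' Convenience wrapper around [generate_population()] returning the n x 11
#' symptom matrix.
#'
#' @inheritParams generate_population
#' @return n x 11 numeric matrix.
#' @export
generate_symptoms <- function(config) {
  generate_population(config)$symptoms
}

#' Generate IQ covariates from latent factor draws
#'
#' Each covariate is a weighted combination of the latent p, Ext and Int
#' draws plus independent normal noise. The weight vector solves
#' \eqn{\Phi w = r} (with \eqn{\Phi} the latent correlation matrix and
#' \eqn{r} the target correlation vector) and the noise variance is
#' \eqn{1 - r'\Phi^{-1} r}, so each covariate has unit variance and the
#' target correlations with the factors before the final affine rescale to
#' the requested mean and SD.
#'
#' @param latent_scores n x k matrix including columns named as in the rows
#'   of `targets`' column names (typically p, Ext, Int).
#' @param targets Covariate x factor matrix of target correlations (see
#'   [covariate_targets()]).
#' @param phi Latent correlation matrix over the target factors; defaults to
#'   the sample correlation of `latent_scores`.
#' @param mean,sd Output scale (default 100 / 15).
#' @return n x nrow(targets) matrix of covariate scores.
#' @export
generate_covariates <- function(latent_scores, targets, phi = NULL,
                                mean = 100, sd = 15) {
  fac <- colnames(targets)
  if (!all(fac %in% colnames(latent_scores)))
    stop("latent_scores must contain columns: ", paste(fac, collapse = ", "))
  eta <- latent_scores[, fac, drop = FALSE]
  if (is.null(phi)) phi <- stats::cor(eta)
  if (is.null(dimnames(phi))) dimnames(phi) <- list(fac, fac)
  phi <- phi[fac, fac, drop = FALSE]
  n <- nrow(eta)
  out <- matrix(NA_real_, n, nrow(targets),
                dimnames = list(NULL, rownames(targets)))
  for (v in seq_len(nrow(targets))) {
    r <- targets[v, ]
    w <- solve(phi, r)
    r2 <- sum(r * w)
    if (r2 >= 1)
      stop("covariate '", rownames(targets)[v],
           "' targets imply multiple R-squared >= 1")
    y <- as.numeric(eta %*% w) + stats::rnorm(n, sd = sqrt(1 - r2))
    out[, v] <- mean + sd * y
  }
  out
}

#' Write / read a population dataset
#'
#' `write_population()` writes a headered CSV (subject id, 11 symptom and 4
#' covariate columns) plus a JSON sidecar recording the generating
#' configuration (n, skew targets, seed, generator mode).
#' `read_population()` reads the CSV back.
#'
#' @param population A `bfs_population`.
#' @param file Path of the CSV to write; the sidecar gets extension `.json`.
#' @return `write_population()` the file path, invisibly;
#'   `read_population()` a data frame.
#' @export
write_population <- function(population, file) {
  stopifnot(inherits(population, "bfs_population"))
  df <- data.frame(subject = seq_len(nrow(population$symptoms)),
                   population$symptoms, check.names = FALSE)
  if (!is.null(population$covariates)) df <- cbind(df, population$covariates)
  utils::write.csv(df, file, row.names = FALSE)
  cfg <- population$config
  meta <- list(n_subjects = cfg$n_subjects,
               target_skew = cfg$target_skew,
               target_excess_kurtosis = cfg$target_excess_kurtosis,
               vale_maurelli = cfg$vale_maurelli,
               model_id = cfg$model$model_id,
               seed = cfg$seed)
  jsonlite::write_json(meta, sub("\\.csv$", ".json", file),
                       auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname write_population
#' @export
read_population <- function(file) {
  utils::read.csv(file, check.names = FALSE)
}
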