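#' Disorder indicators and symptom domains
#'
#' The eleven disorder symptom variables used throughout the package, in their
#' fixed canonical order, and their assignment to the three symptom domains
#' (externalising: substance use and conduct; internalising: mood and anxiety;
#' thought disorder: obsessive-compulsive disorder, mania, schizophrenia).
#'
#' @return `psycho_indicators()` returns a character vector of length 11;
#'   `disorder_domains()` a named list with elements `ext`, `int`, `tht`.
#' @export
psycho_indicators <- function() {
  c("alc", "cann", "hd", "tob", "cd",
    "dep", "gad", "fears",
    "ocd", "mania", "schiz")
}

#' @rdname psycho_indicators
#' @export
disorder_domains <- function() {
  list(ext = c("alc", "cann", "hd", "tob", "cd"),
       int = c("dep", "gad", "fears"),
       tht = c("ocd", "mania", "schiz"))
}

#' Model identifiers
#' @return Character vector of the four structural model ids.
#' @export
model_ids <- function() {
  c("A_correlated", "B_bifactor", "C_revised_bifactor", "D_single")
}

#' Build a structural model template
#'
#' Encodes one of the four structural models of psychopathology as a
#' declarative template: which loadings are free, which factor correlations
#' are free, and which factor pairs are fixed orthogonal. Identification is by
#' unit factor variance, so all parameters live on the standardized metric.
#'
#' The four models are:
#' \describe{
#'   \item{`A_correlated`}{Three correlated specific factors
#'     (Ext over the 5 externalising disorders, Int over the 3 internalising,
#'     Tht over the 3 thought disorders) with all three inter-factor
#'     correlations free; no general factor.}
#'   \item{`B_bifactor`}{Full bifactor: a general p-factor over all 11
#'     indicators plus Ext, Int and Tht specific factors; p is orthogonal to
#'     the specifics and the three specific-specific correlations are free.}
#'   \item{`C_revised_bifactor`}{Revised bifactor: p over all 11 indicators,
#'     Ext and Int specifics only (the thought disorders load on p alone);
#'     p orthogonal to the specifics, Ext-Int correlation free.}
#'   \item{`D_single`}{A single general factor over all 11 indicators.}
#' }
#'
#' @param model_id One of [model_ids()].
#' @return An object of class `bfs_model`: a list with `model_id`,
#'   `indicators`, `factor_labels`, `loading_pattern` (11 x k logical matrix),
#'   `free_factor_correlations` (two-column character matrix of factor pairs),
#'   and `fixed_orthogonal` (ditto, pairs constrained to zero covariance).
#' @examples
#' m <- build_model("C_revised_bifactor")
#' model_df(m)  # 35
#' @export
build_model <- function(model_id) {
  model_id <- match.arg(model_id, model_ids())
  ind <- psycho_indicators()
  dom <- disorder_domains()
  pat <- function(factors, on) {
    m <- matrix(FALSE, 11, length(factors),
                dimnames = list(ind, factors))
    for (f in names(on)) m[on[[f]], f] <- TRUE
    m
  }
  pairs <- function(...) {
    x <- list(...)
    if (!length(x)) return(matrix(character(), 0, 2))
    do.call(rbind, x)
  }
  spec <- switch(model_id,
    A_correlated = list(
      factor_labels = c("Ext", "Int", "Tht"),
      loading_pattern = pat(c("Ext", "Int", "Tht"),
                            list(Ext = dom$ext, Int = dom$int, Tht = dom$tht)),
      free_factor_correlations = pairs(c("Ext", "Int"), c("Ext", "Tht"),
                                       c("Int", "Tht")),
      fixed_orthogonal = pairs()),
    B_bifactor = list(
      factor_labels = c("p", "Ext", "Int", "Tht"),
      loading_pattern = pat(c("p", "Ext", "Int", "Tht"),
                            list(p = ind, Ext = dom$ext, Int = dom$int,
                                 Tht = dom$tht)),
      free_factor_correlations = pairs(c("Ext", "Int"), c("Ext", "Tht"),
                                       c("Int", "Tht")),
      fixed_orthogonal = pairs(c("p", "Ext"), c("p", "Int"), c("p", "Tht"))),
    C_revised_bifactor = list(
      factor_labels = c("p", "Ext", "Int"),
      loading_pattern = pat(c("p", "Ext", "Int"),
                            list(p = ind, Ext = dom$ext, Int = dom$int)),
      free_factor_correlations = pairs(c("Ext", "Int")),
      fixed_orthogonal = pairs(c("p", "Ext"), c("p", "Int"))),
    D_single = list(
      factor_labels = "p",
      loading_pattern = pat("p", list(p = ind)),
      free_factor_correlations = pairs(),
      fixed_orthogonal = pairs())
  )
  structure(c(list(model_id = model_id, indicators = ind), spec),
            class = "bfs_model")
}

#' @export
print.bfs_model <- function(x, ...) {
  cat("<bfs_model>", x$model_id, "\n")
  cat("  factors:", paste(x$factor_labels, collapse = ", "), "\n")
  cat("  free loadings:", sum(x$loading_pattern),
      "| free factor correlations:", nrow(x$free_factor_correlations),
      "| df:", model_df(x), "\n")
  invisible(x)
}

#' Count free parameters of a model template
#'
#' Free loadings + free factor correlations + 11 residual variances
#' (factor variances are fixed to 1 for identification; means are saturated).
#'
#' @param spec A `bfs_model`.
#' @return Integer count.
#' @export
n_free_parameters <- function(spec) {
  stopifnot(inherits(spec, "bfs_model"))
  sum(spec$loading_pattern) + nrow(spec$free_factor_correlations) +
    length(spec$indicators)
}

#' Degrees of freedom of a covariance-structure model
#'
#' For p = 11 indicators there are p(p+1)/2 = 66 non-redundant moments;
#' df = 66 minus the free-parameter count. Yields 41 (A), 30 (B), 35 (C)
#' and 44 (D).
#'
#' @inheritParams n_free_parameters
#' @return Integer degrees of freedom.
#' @export
model_df <- function(spec) {
  stopifnot(inherits(spec, "bfs_model"))
  p <- length(spec$indicators)
  as.integer(p * (p + 1) / 2 - n_free_parameters(spec))
}

#' Construct a parameter set for a model template
#'
#' Packages standardized loadings, factor correlations and residual variances
#' conforming to a model template's pattern. When `residual_variances` is
#' omitted, residuals are set to 1 minus each indicator's communality (the
#' fully standardized convention used by the generating fixtures).
#'
#' @param spec A `bfs_model`.
#' @param loadings Numeric 11 x k matrix (zeros off-pattern), or a named list
#'   `factor -> named loading vector`.
#' @param factor_correlations Symmetric k x k matrix with unit diagonal; may
#'   be omitted for single-factor or all-orthogonal models.
#' @param residual_variances Optional length-11 vector.
#' @return An object of class `bfs_params` with elements `loadings`,
#'   `factor_correlations`, `residual_variances`.
#' @export
make_params <- function(spec, loadings, factor_correlations = NULL,
                        residual_variances = NULL) {
  stopifnot(inherits(spec, "bfs_model"))
  k <- length(spec$factor_labels)
  if (is.list(loadings)) {
    L <- matrix(0, length(spec$indicators), k,
                dimnames = list(spec$indicators, spec$factor_labels))
    for (f in names(loadings)) L[names(loadings[[f]]), f] <- loadings[[f]]
    loadings <- L
  }
  loadings <- as.matrix(loadings)
  dimnames(loadings) <- list(spec$indicators, spec$factor_labels)
  if (any(loadings[!spec$loading_pattern] != 0))
    stop("nonzero loading outside the model's free pattern")
  if (is.null(factor_correlations)) factor_correlations <- diag(k)
  Phi <- as.matrix(factor_correlations)
  dimnames(Phi) <- list(spec$factor_labels, spec$factor_labels)
  if (any(abs(diag(Phi) - 1) > 1e-12))
    stop("factor correlation matrix must have unit diagonal")
  if (max(abs(Phi - t(Phi))) > 1e-12) stop("factor correlations not symmetric")
  fo <- spec$fixed_orthogonal
  if (nrow(fo) && any(Phi[fo] != 0))
    stop("nonzero correlation for an orthogonal factor pair")
  if (is.null(residual_variances)) {
    communality <- diag(loadings %*% Phi %*% t(loadings))
    if (any(communality >= 1))
      stop("communality >= 1: standardized residual variances undefined")
    residual_variances <- 1 - communality
  }
  residual_variances <- stats::setNames(as.numeric(residual_variances),
                                        spec$indicators)
  structure(list(loadings = loadings, factor_correlations = Phi,
                 residual_variances = residual_variances),
            class = "bfs_params")
}

#' Model-implied covariance matrix
#'
#' The standard covariance-structure implied moment
#' \eqn{\Sigma = \Lambda \Phi \Lambda' + \Theta}. For a fully standardized
#' parameter set (residuals = 1 - communality) the diagonal is exactly 1, so
#' the result is the implied correlation matrix.
#'
#' @param spec A `bfs_model`.
#' @param params A `bfs_params` conforming to `spec`.
#' @return Symmetric 11 x 11 matrix with indicator dimnames.
#' @export
implied_covariance <- function(spec, params) {
  stopifnot(inherits(spec, "bfs_model"), inherits(params, "bfs_params"))
  L <- params$loadings
  if (!all(dim(L) == dim(spec$loading_pattern)))
    stop("loading matrix dimensions do not match the model template")
  S <- L %*% params$factor_correlations %*% t(L) +
    diag(params$residual_variances, length(spec$indicators))
  dimnames(S) <- list(spec$indicators, spec$indicators)
  (S + t(S)) / 2
}

.read_fixture <- function(file) {
  path <- system.file("extdata", file, package = "bifactorsim")
  if (path == "") path <- file.path("inst", "extdata", file)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Published generating parameters
#'
#' Loads the packaged generating fixtures transcribed from the published
#' Dunedin-cohort revised bifactor solution (`"caspi"`, Ext~Int = -.471) and
#' from the fitted full simulated population (`"simdata"`, Ext~Int = -.387),
#' for the revised bifactor structure or the correlated factors structure.
#'
#' @param set `"caspi"` or `"simdata"`.
#' @param model `"revised_bifactor"` (default) or `"correlated"`.
#' @return A `bfs_params` on the fully standardized metric (residual
#'   variances = 1 - communality).
#' @export
generating_parameters <- function(set = c("caspi", "simdata"),
                                  model = c("revised_bifactor", "correlated")) {
  set <- match.arg(set)
  model <- match.arg(model)
  spec <- build_model(if (model == "revised_bifactor")
    "C_revised_bifactor" else "A_correlated")
  lo <- .read_fixture("generating_loadings.csv")
  lo <- lo[lo$source == set & lo$model == model, ]
  L <- matrix(0, 11, length(spec$factor_labels),
              dimnames = list(spec$indicators, spec$factor_labels))
  L[cbind(match(lo$indicator, spec$indicators),
          match(lo$factor, spec$factor_labels))] <- lo$loading
  fc <- .read_fixture("factor_correlations.csv")
  fc <- fc[fc$source == set & fc$model == model, ]
  Phi <- diag(length(spec$factor_labels))
  dimnames(Phi) <- list(spec$factor_labels, spec$factor_labels)
  for (i in seq_len(nrow(fc))) {
    Phi[fc$factor_1[i], fc$factor_2[i]] <- fc$value[i]
    Phi[fc$factor_2[i], fc$factor_1[i]] <- fc$value[i]
  }
  make_params(spec, L, Phi)
}

#' Published covariate (IQ subscale) target correlations
#'
#' Target bivariate correlations between the four IQ composite subscales
#' (VC, PR, WM, PS; scale mean 100, SD 15) and the p, Ext and Int factors,
#' as transcribed for the `"caspi"` and `"simdata"` rows of the published
#' comparison table.
#'
#' @param set `"caspi"` or `"simdata"`.
#' @return A 4 x 3 numeric matrix, rows VC/PR/WM/PS, columns p/Ext/Int.
#' @export
covariate_targets <- function(set = c("caspi", "simdata")) {
  set <- match.arg(set)
  ct <- .read_fixture("covariate_targets.csv")
  ct <- ct[ct$source == set, ]
  covs <- c("VC", "PR", "WM", "PS")
  fac <- c("p", "Ext", "Int")
  m <- matrix(NA_real_, 4, 3, dimnames = list(covs, fac))
  m[cbind(match(ct$covariate, covs), match(ct$factor, fac))] <- ct$value
  m
}
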