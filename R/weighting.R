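#' NC-based variable weights (NCVW)
#'
#' Builds the NC affinity matrix over the M variables plus the response
#' (each treated as an N-vector) and extracts the response column: the
#' weight of variable m is the number of queries for which the pair
#' (variable m, response) was flagged as sharing a correlation structure.
#' Weights are nonnegative counts; by default they are normalized by the
#' maximum count so the largest weight is 1 (raw counts grow with M, and
#' PLS on centered data responds to relative, not absolute, column scales).
#'
#' @param dataset a [spectra_dataset()] with a non-constant response.
#' @param config an [nc_config()]; `gamma = 0.99` is the recommended
#'   default and the method's only tuning parameter.
#' @param normalization `"max"` (default), `"sum"`, or `"none"` (raw
#'   counts).
#' @return object of class `weight_vector`: `weights` (length M, named by
#'   variable label), `raw` (unnormalized), `source = "ncvw"`, `gamma`,
#'   `normalization`.
#' @export
ncvw_weights <- function(dataset, config = nc_config(),
                         normalization = c("max", "sum", "none")) {
  stopifnot(inherits(dataset, "spectra_dataset"))
  normalization <- match.arg(normalization)
  if (is.null(dataset$y)) stop("dataset has no response", call. = FALSE)
  if (stats::sd(dataset$y) == 0) {
    stop("response is constant: NCVW weights are undefined", call. = FALSE)
  }
  if (ncol(dataset$X) < 2L) stop("need at least 2 variables", call. = FALSE)
  aff <- variable_affinity(dataset, include_response = TRUE, config = config)
  m <- ncol(dataset$X)
  raw <- aff$counts[seq_len(m), m + 1L]
  new_weight_vector(raw, normalization, source = "ncvw",
                    labels = dataset$wavelengths, gamma = config$gamma)
}

new_weight_vector <- function(raw, normalization, source, labels, gamma = NULL) {
  w <- raw
  if (normalization == "max" && max(w) > 0) w <- w / max(w)
  if (normalization == "sum" && sum(w) > 0) w <- w / sum(w)
  structure(list(weights = stats::setNames(as.numeric(w), as.character(labels)),
                 raw = as.numeric(raw), source = source,
                 normalization = normalization, gamma = gamma),
            class = "weight_vector")
}

#' @export
print.weight_vector <- function(x, ...) {
  cat(sprintf("weight_vector (%s%s): %d variables, %d nonzero, max raw %g\n",
              x$source, if (!is.null(x$gamma)) sprintf(", gamma = %g", x$gamma) else "",
              length(x$weights), sum(x$weights > 0), max(x$raw)))
  invisible(x)
}

#' Correlation-coefficient variable weights (CCVW)
#'
#' The baseline weighting scheme: each variable's weight is the Pearson
#' correlation between that (centered) column and the response,
#' `c_m = y' x_m / (||y|| ||x_m||)`. The absolute value is used as the
#' multiplicative weight (a negative weight would only flip a column's
#' sign, which PLS absorbs); the signed correlations are kept in `raw`.
#' Zero-variance columns get weight 0.
#'
#' @param dataset a [spectra_dataset()] with a non-constant response.
#' @param normalization `"none"` (default; correlations already lie in
#'   [0, 1] after the absolute value), `"max"`, or `"sum"`.
#' @return a `weight_vector` with `source = "ccvw"`.
#' @export
ccvw_weights <- function(dataset, normalization = c("none", "max", "sum")) {
  stopifnot(inherits(dataset, "spectra_dataset"))
  normalization <- match.arg(normalization)
  if (is.null(dataset$y)) stop("dataset has no response", call. = FALSE)
  if (stats::sd(dataset$y) == 0) {
    stop("response is constant: CCVW weights are undefined", call. = FALSE)
  }
  yc <- dataset$y - mean(dataset$y)
  Xc <- sweep(dataset$X, 2, colMeans(dataset$X))
  xn <- sqrt(colSums(Xc^2))
  cc <- as.numeric(crossprod(Xc, yc)) / (sqrt(sum(yc^2)) * ifelse(xn > 0, xn, 1))
  cc[xn == 0] <- 0
  out <- new_weight_vector(abs(cc), normalization, source = "ccvw",
                           labels = dataset$wavelengths)
  out$raw <- cc
  out
}

#' Apply multiplicative variable weights to a dataset
#'
#' Multiplies every sample's m-th variable by `w_m` (element-wise product
#' `z_n = w o x_n`). Variable labels are preserved; zero-weight columns
#' become identically zero (they are kept, not dropped, so the wavelength
#' axis and model dimension stay stable).
#'
#' @param dataset a [spectra_dataset()] or plain matrix.
#' @param w a `weight_vector` or numeric vector of length M.
#' @return the weighted dataset (same class as the input).
#' @export
apply_weights <- function(dataset, w) {
  wv <- if (inherits(w, "weight_vector")) w$weights else as.numeric(w)
  if (inherits(dataset, "spectra_dataset")) {
    if (length(wv) != ncol(dataset$X)) stop("weight length mismatch", call. = FALSE)
    out <- dataset
    out$X <- sweep(dataset$X, 2, wv, `*`)
    return(out)
  }
  X <- as_numeric_matrix(dataset, "dataset")
  if (length(wv) != ncol(X)) stop("weight length mismatch", call. = FALSE)
  sweep(X, 2, wv, `*`)
}

#' Weighted-PLS pipeline: weight, select components by CV, fit
#'
#' Applies a weight vector to the dataset, selects the number of latent
#' variables by cross-validation on the weighted (centering-only) data, and
#' fits the final PLS model. The weights are stored in the returned object
#' and re-applied automatically when predicting new samples.
#'
#' @param dataset a [spectra_dataset()] with response.
#' @param weights a `weight_vector` (e.g. from [ncvw_weights()]).
#' @param cv_folds cross-validation folds.
#' @param K_max cap on the number of latent variables (default as in
#'   [select_components_cv()]).
#' @param seed fold-assignment seed.
#' @return object of class `weighted_pls`: `model` (`pls_model`),
#'   `weights` (`weight_vector`), `ncomp`.
#' @export
weighted_pls <- function(dataset, weights, cv_folds = 10L, K_max = NULL,
                         seed = 1L) {
  stopifnot(inherits(dataset, "spectra_dataset"),
            inherits(weights, "weight_vector"))
  z <- apply_weights(dataset, weights)
  k <- select_components_cv(z, folds = cv_folds, seed = seed,
                            K_max = clamp_K_max(K_max, z, cv_folds))
  model <- suppressWarnings(fit_pls(z, ncomp = as.integer(k)))
  structure(list(model = model, weights = weights, ncomp = model$ncomp),
            class = "weighted_pls")
}

#' @export
predict.weighted_pls <- function(object, newdata, ...) {
  if (inherits(newdata, "spectra_dataset")) newdata <- newdata$X
  predict(object$model, apply_weights(newdata, object$weights), ...)
}

#' @export
print.weighted_pls <- function(x, ...) {
  cat(sprintf("weighted_pls (%s): %d latent variable(s), %d variables\n",
              x$weights$source, x$ncomp, length(x$weights$weights)))
  invisible(x)
}

#' NCVW soft-sensor pipeline
#'
#' The full NC-based variable weighting workflow: compute NCVW weights
#' (single tuning parameter `gamma`, default 0.99), weight the variables,
#' pick the number of latent variables by cross-validation, and fit the
#' final PLS model on the weighted data.
#'
#' @inheritParams ncvw_weights
#' @inheritParams weighted_pls
#' @return a `weighted_pls` object.
#' @examples
#' sim <- simulate_spectra(sim_spec(n_samples = 60, n_wavelengths = 40,
#'                                  seed = 7))
#' fit <- ncvw_pipeline(sim$dataset, cv_folds = 5)
#' fit$ncomp
#' @export
ncvw_pipeline <- function(dataset, config = nc_config(),
                          normalization = "max", cv_folds = 10L,
                          K_max = NULL, seed = 1L) {
  w <- ncvw_weights(dataset, config = config, normalization = normalization)
  weighted_pls(dataset, w, cv_folds = cv_folds, K_max = K_max, seed = seed)
}

#' CCVW soft-sensor pipeline
#'
#' The correlation-coefficient weighting baseline: weight each variable by
#' its absolute correlation with the response, then cross-validated PLS.
#'
#' @inheritParams ccvw_weights
#' @inheritParams weighted_pls
#' @return a `weighted_pls` object.
#' @export
ccvw_pipeline <- function(dataset, normalization = "none", cv_folds = 10L,
                          K_max = NULL, seed = 1L) {
  w <- ccvw_weights(dataset, normalization = normalization)
  weighted_pls(dataset, w, cv_folds = cv_folds, K_max = K_max, seed = seed)
}

#' Export weights as a two-column CSV
#'
#' @param w a `weight_vector`.
#' @param file output path.
#' @return invisibly, `w`.
#' @export
write_weights_csv <- function(w, file) {
  stopifnot(inherits(w, "weight_vector"))
  utils::write.csv(data.frame(variable = names(w$weights), weight = w$weights),
                   file, row.names = FALSE)
  invisible(w)
}
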