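#' Paired spectra / response container
#'
#' Bundles a numeric spectra matrix (rows = samples, columns = variables,
#' typically wavelengths) with a per-sample response vector (e.g. API
#' content), the variable axis labels, and optional sample identifiers.
#' All modelling functions in the package accept this container.
#'
#' @param X numeric matrix, N samples by M variables.
#' @param y numeric response vector of length N, or `NULL` for
#'   prediction-only data.
#' @param wavelengths numeric or character labels for the M variables;
#'   defaults to column names of `X` or `1:M`.
#' @param sample_ids optional character vector of length N.
#' @return An object of class `spectra_dataset` with elements `X`, `y`,
#'   `wavelengths`, `sample_ids`.
#' @examples
#' d <- spectra_dataset(matrix(rnorm(20), 4, 5), rnorm(4))
#' dim(d$X)
#' @export
spectra_dataset <- function(X, y = NULL, wavelengths = NULL, sample_ids = NULL) {
  X <- as_numeric_matrix(X)
  n <- nrow(X); m <- ncol(X)
  if (!is.null(y)) {
    y <- as.numeric(y)
    if (length(y) != n) stop("length(y) must equal nrow(X)", call. = FALSE)
    if (anyNA(y) || any(!is.finite(y))) stop("`y` contains non-finite values", call. = FALSE)
  }
  if (is.null(wavelengths)) {
    wavelengths <- if (!is.null(colnames(X))) colnames(X) else as.character(seq_len(m))
  }
  if (length(wavelengths) != m) stop("wavelengths must have one label per column", call. = FALSE)
  if (!is.null(sample_ids) && length(sample_ids) != n) {
    stop("sample_ids must have one id per row", call. = FALSE)
  }
  colnames(X) <- as.character(wavelengths)
  structure(list(X = X, y = y, wavelengths = wavelengths,
                 sample_ids = sample_ids),
            class = "spectra_dataset")
}

#' @export
print.spectra_dataset <- function(x, ...) {
  cat(sprintf("spectra_dataset: %d samples x %d variables%s\n",
              nrow(x$X), ncol(x$X),
              if (is.null(x$y)) " (no response)" else ""))
  invisible(x)
}

#' @export
dim.spectra_dataset <- function(x) dim(x$X)

#' Subset a spectra dataset by sample and/or variable index
#'
#' @param dataset a [spectra_dataset()].
#' @param samples integer/logical row index (default: all).
#' @param variables integer/logical column index (default: all).
#' @return a `spectra_dataset`.
#' @export
subset_dataset <- function(dataset, samples = NULL, variables = NULL) {
  stopifnot(inherits(dataset, "spectra_dataset"))
  if (is.null(samples)) samples <- seq_len(nrow(dataset$X))
  if (is.null(variables)) variables <- seq_len(ncol(dataset$X))
  spectra_dataset(dataset$X[samples, variables, drop = FALSE],
                  y = if (is.null(dataset$y)) NULL else dataset$y[samples],
                  wavelengths = dataset$wavelengths[variables],
                  sample_ids = if (is.null(dataset$sample_ids)) NULL else dataset$sample_ids[samples])
}

#' Split a dataset into training and validation parts
#'
#' @param dataset a [spectra_dataset()].
#' @param n_train number of training samples.
#' @param seed integer seed for the random assignment; `NULL` takes the
#'   first `n_train` rows in order.
#' @return list with elements `train` and `validation`.
#' @export
split_dataset <- function(dataset, n_train, seed = NULL) {
  stopifnot(inherits(dataset, "spectra_dataset"))
  n <- nrow(dataset$X)
  check_scalar(n_train, "n_train", lower = 1, upper = n - 1, integer = TRUE)
  idx <- if (is.null(seed)) seq_len(n_train) else
    with_local_seed(seed, sample.int(n, n_train))
  list(train = subset_dataset(dataset, samples = idx),
       validation = subset_dataset(dataset, samples = setdiff(seq_len(n), idx)))
}

#' Read spectra (and optionally a response) from CSV
#'
#' The spectra CSV has a header row of variable labels (wavelengths in nm)
#' and one row per sample; an optional first column holds sample IDs (it is
#' treated as IDs whenever it is non-numeric or named `sample`/`id`). The
#' response CSV has a sample ID column plus one numeric value column, or a
#' single numeric column matched by row order.
#'
#' @param spectra_file path to the spectra CSV.
#' @param response_file optional path to the response CSV.
#' @return a [spectra_dataset()].
#' @export
read_spectra_csv <- function(spectra_file, response_file = NULL) {
  df <- utils::read.csv(spectra_file, check.names = FALSE)
  ids <- NULL
  first <- names(df)[1L]
  if (!is.numeric(df[[1L]]) || tolower(first) %in% c("sample", "sample_id", "id")) {
    ids <- as.character(df[[1L]])
    df <- df[, -1L, drop = FALSE]
  }
  X <- as.matrix(df)
  wl <- suppressWarnings(as.numeric(names(df)))
  labels <- if (anyNA(wl)) names(df) else wl
  y <- NULL
  if (!is.null(response_file)) {
    rf <- utils::read.csv(response_file, check.names = FALSE)
    vcol <- which(vapply(rf, is.numeric, logical(1)))
    if (length(vcol) == 0L) stop("response CSV has no numeric column", call. = FALSE)
    y <- rf[[vcol[length(vcol)]]]
    if (!is.null(ids) && ncol(rf) >= 2L && !is.numeric(rf[[1L]])) {
      pos <- match(ids, as.character(rf[[1L]]))
      if (anyNA(pos)) stop("response CSV is missing some sample IDs", call. = FALSE)
      y <- y[pos]
    }
  }
  spectra_dataset(X, y = y, wavelengths = labels, sample_ids = ids)
}

#' Write a spectra dataset to CSV
#'
#' @param dataset a [spectra_dataset()].
#' @param spectra_file output path for the spectra CSV.
#' @param response_file optional output path for the response CSV.
#' @return invisibly, `dataset`.
#' @export
write_spectra_csv <- function(dataset, spectra_file, response_file = NULL) {
  stopifnot(inherits(dataset, "spectra_dataset"))
  df <- as.data.frame(dataset$X, check.names = FALSE)
  ids <- dataset$sample_ids
  if (is.null(ids)) ids <- sprintf("s%03d", seq_len(nrow(dataset$X)))
  out <- cbind(data.frame(sample = ids, check.names = FALSE), df)
  utils::write.csv(out, spectra_file, row.names = FALSE)
  if (!is.null(response_file)) {
    if (is.null(dataset$y)) stop("dataset has no response to write", call. = FALSE)
    utils::write.csv(data.frame(sample = ids, value = dataset$y),
                     response_file, row.names = FALSE)
  }
  invisible(dataset)
}
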