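#' Nearest-correlation (NC) method configuration
#'
#' The NC method translates all items so that a query item sits at the
#' origin and flags pairs of translated items whose correlation coefficient
#' exceeds `gamma` in absolute value; such pairs share an (approximately)
#' linear structure passing through the query. `gamma = 0.99` is the
#' recommended default.
#'
#' @param gamma correlation threshold in (0, 1].
#' @param method similarity used on the translated vectors: `"pearson"`
#'   (centered correlation coefficient, default) or `"cosine"` (uncentered;
#'   the strict "collinear through the origin" geometric reading).
#' @return an object of class `nc_config`.
#' @export
nc_config <- function(gamma = 0.99, method = c("pearson", "cosine")) {
  check_scalar(gamma, "gamma", lower = 0, upper = 1, open_lower = TRUE)
  method <- match.arg(method)
  structure(list(gamma = gamma, method = method), class = "nc_config")
}

# Similarity matrix between rows of the translated matrix U.
# Rows that are (numerically) zero, or constant under the Pearson reading,
# are marked invalid: a correlation with them is treated as "not similar".
nc_similarity <- function(U, method) {
  norms <- sqrt(rowSums(U^2))
  typical <- max(norms)
  invalid <- if (typical > 0) norms <= 1e-12 * typical else rep(TRUE, nrow(U))
  if (method == "pearson") {
    V <- U - rowMeans(U)
    vn <- sqrt(rowSums(V^2))
    invalid <- invalid | vn <= 1e-12 * norms
    vn[vn == 0] <- 1
    C <- tcrossprod(V / vn)
  } else {
    nz <- norms
    nz[nz == 0] <- 1
    C <- tcrossprod(U / nz)
  }
  C[invalid, ] <- 0
  C[, invalid] <- 0
  C
}

#' NC similarity search: pairs sharing the query's correlation structure
#'
#' Translates every item by the query item and returns the unordered pairs
#' (k, l), both distinct from the query, whose translated vectors have
#' `|correlation| >= gamma`. Pairs involving a zero-norm translated vector
#' (including the query itself) are never returned.
#'
#' @param items numeric matrix with one item per row (all rows the same
#'   length >= 2; at least 3 rows), or a list of equal-length numeric
#'   vectors.
#' @param query_index row index of the query item.
#' @param config an [nc_config()].
#' @return integer matrix with columns `k`, `l` (k < l), one row per
#'   flagged pair; zero rows when none qualify.
#' @examples
#' pts <- rbind(q = c(0, 0), a = c(1, 1), b = c(2, 2), c = c(1, 0))
#' nc_similar_pairs(pts, 1, nc_config(0.99, method = "cosine"))
#' @export
nc_similar_pairs <- function(items, query_index, config = nc_config()) {
  stopifnot(inherits(config, "nc_config"))
  items <- items_as_matrix(items)
  q <- nrow(items)
  check_scalar(query_index, "query_index", lower = 1, upper = q, integer = TRUE)
  C <- nc_similarity(sweep(items, 2, items[query_index, ]), config$method)
  hit <- abs(C) >= config$gamma
  hit[query_index, ] <- FALSE
  hit[, query_index] <- FALSE
  diag(hit) <- FALSE
  idx <- which(hit & upper.tri(hit), arr.ind = TRUE)
  colnames(idx) <- c("k", "l")
  idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
}

items_as_matrix <- function(items) {
  if (is.list(items)) items <- do.call(rbind, items)
  items <- as_numeric_matrix(items, "items")
  if (nrow(items) < 3L) stop("need at least 3 items", call. = FALSE)
  if (ncol(items) < 2L) stop("items must have length >= 2", call. = FALSE)
  items
}

#' NC affinity matrix over a set of items
#'
#' Runs the NC similarity search with every item in turn as the query and
#' accumulates, for each pair (k, l), the number of queries that flagged it.
#' The result is a symmetric nonnegative integer matrix with zero diagonal;
#' each off-diagonal count is at most Q - 2, since a pair can only be
#' flagged by queries that are neither of its members.
#'
#' @inheritParams nc_similar_pairs
#' @return an object of class `affinity_matrix` with elements `counts`
#'   (Q x Q integer-valued matrix) and `gamma`.
#' @export
build_affinity <- function(items, config = nc_config()) {
  stopifnot(inherits(config, "nc_config"))
  items <- items_as_matrix(items)
  q <- nrow(items)
  counts <- matrix(0, q, q)
  for (L in seq_len(q)) {
    C <- nc_similarity(sweep(items, 2, items[L, ]), config$method)
    hit <- abs(C) >= config$gamma
    hit[L, ] <- FALSE
    hit[, L] <- FALSE
    diag(hit) <- FALSE
    counts <- counts + hit
  }
  dimnames(counts) <- list(rownames(items), rownames(items))
  structure(list(counts = counts, gamma = config$gamma, method = config$method),
            class = "affinity_matrix")
}

#' @export
print.affinity_matrix <- function(x, ...) {
  cat(sprintf("affinity_matrix: %d items, gamma = %g, %d nonzero pairs\n",
              nrow(x$counts), x$gamma, sum(x$counts[upper.tri(x$counts)] > 0)))
  invisible(x)
}

#' NC affinity between variables (columns) of a dataset
#'
#' Treats each column of the spectra matrix — and, when requested, the
#' response — as an N-vector item and builds the NC affinity matrix over
#' those items. With `include_response = TRUE` the result is
#' (M+1) x (M+1) and the last row/column corresponds to the response; its
#' off-diagonal entries are the correlation-similarity counts between each
#' variable and the response that NCVW uses as weights.
#'
#' @param dataset a [spectra_dataset()] (response required only when
#'   `include_response = TRUE`), or a plain numeric matrix.
#' @param include_response append the response as an extra item.
#' @param config an [nc_config()].
#' @return an `affinity_matrix` of size M x M or (M+1) x (M+1).
#' @export
variable_affinity <- function(dataset, include_response = FALSE,
                              config = nc_config()) {
  if (!inherits(dataset, "spectra_dataset")) dataset <- spectra_dataset(dataset)
  if (nrow(dataset$X) < 3L) stop("need at least 3 samples", call. = FALSE)
  items <- t(dataset$X)
  rownames(items) <- as.character(dataset$wavelengths)
  if (include_response) {
    if (is.null(dataset$y)) stop("dataset has no response", call. = FALSE)
    items <- rbind(items, response = dataset$y)
  }
  build_affinity(items, config)
}

#' Export an affinity matrix as labelled dense CSV
#'
#' @param affinity an [build_affinity()] result.
#' @param file output path.
#' @return invisibly, `affinity`.
#' @export
write_affinity_csv <- function(affinity, file) {
  stopifnot(inherits(affinity, "affinity_matrix"))
  labels <- rownames(affinity$counts)
  if (is.null(labels)) labels <- as.character(seq_len(nrow(affinity$counts)))
  df <- cbind(data.frame(item = labels),
              as.data.frame(affinity$counts, check.names = FALSE))
  utils::write.csv(df, file, row.names = FALSE)
  invisible(affinity)
}
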