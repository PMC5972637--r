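# Internal helpers shared across modules.

# Run `expr` under a local RNG seed without disturbing the caller's stream.
with_local_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

as_numeric_matrix <- function(x, arg = "X") {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop(sprintf("`%s` must be numeric", arg), call. = FALSE)
  if (anyNA(x) || any(!is.finite(x))) {
    stop(sprintf("`%s` contains non-finite values", arg), call. = FALSE)
  }
  x
}

check_scalar <- function(x, arg, lower = -Inf, upper = Inf,
                         integer = FALSE, open_lower = FALSE) {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x)) {
    stop(sprintf("`%s` must be a finite numeric scalar", arg), call. = FALSE)
  }
  if (integer && x != round(x)) {
    stop(sprintf("`%s` must be an integer", arg), call. = FALSE)
  }
  if (x < lower || x > upper || (open_lower && x <= lower)) {
    stop(sprintf("`%s` out of range", arg), call. = FALSE)
  }
  invisible(x)
}

soft_threshold <- function(z, t) sign(z) * pmax(abs(z) - t, 0)

# Cap a user-supplied K_max at what the dataset and fold sizes support.
clamp_K_max <- function(K_max, dataset, folds) {
  if (is.null(K_max)) return(NULL)
  n <- nrow(dataset$X)
  min(K_max, n - ceiling(n / folds) - 1L, ncol(dataset$X))
}
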