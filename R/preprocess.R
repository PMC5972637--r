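#' Savitzky-Golay filter configuration
#'
#' Defaults follow common NIRS practice for first-derivative pretreatment:
#' an 11-point window with a quadratic local polynomial.
#'
#' @param window_length odd integer window size (points).
#' @param poly_order local polynomial degree, >= 1 and < `window_length`.
#' @param deriv_order derivative order, `0 <= deriv_order <= poly_order`
#'   (1 for the usual first-derivative pretreatment).
#' @return an object of class `sg_config`.
#' @export
sg_config <- function(window_length = 11L, poly_order = 2L, deriv_order = 1L) {
  check_scalar(window_length, "window_length", lower = 3, integer = TRUE)
  check_scalar(poly_order, "poly_order", lower = 1, integer = TRUE)
  check_scalar(deriv_order, "deriv_order", lower = 0, integer = TRUE)
  if (window_length %% 2 == 0) {
    stop("`window_length` must be odd", call. = FALSE)
  }
  if (window_length <= poly_order) {
    stop("`window_length` must exceed `poly_order`", call. = FALSE)
  }
  if (deriv_order > poly_order) {
    stop("`deriv_order` must not exceed `poly_order`", call. = FALSE)
  }
  structure(list(window_length = as.integer(window_length),
                 poly_order = as.integer(poly_order),
                 deriv_order = as.integer(deriv_order)),
            class = "sg_config")
}

# Least-squares derivative coefficients for evaluating the deriv-th
# derivative of a degree-p polynomial fitted at `offsets`, at offset 0.
sg_coefficients <- function(offsets, poly_order, deriv_order) {
  p <- min(poly_order, length(offsets) - 1L)
  if (deriv_order > p) return(rep(0, length(offsets)))
  A <- outer(offsets, 0:p, `^`)
  # row (deriv+1) of the pseudoinverse gives the fitted polynomial
  # coefficient of x^deriv; times deriv! it is the derivative at 0
  pinv <- solve(crossprod(A), t(A))
  factorial(deriv_order) * pinv[deriv_order + 1L, ]
}

#' Savitzky-Golay derivative filtering of spectra
#'
#' Filters each row (sample spectrum) independently along the variable axis,
#' returning the `deriv_order`-th derivative of the local least-squares
#' polynomial fit. Interior points use the full centered window; near the
#' edges the window is truncated one-sidedly (no padding), so the output has
#' the same shape as the input. The derivative is per index step: with a
#' uniform wavelength grid this differs from a per-nm derivative only by a
#' global scalar, to which PLS is invariant.
#'
#' @param spectra numeric matrix (N samples x M variables) or a
#'   [spectra_dataset()].
#' @param config an [sg_config()].
#' @return the filtered matrix, or a `spectra_dataset` when one was given.
#' @examples
#' X <- matrix(rep((1:50)^2, 3), nrow = 3, byrow = TRUE)
#' D <- savitzky_golay_derivative(X, sg_config(7, 2, 1))
#' D[1, 25]  # ~ 2 * 25
#' @export
savitzky_golay_derivative <- function(spectra, config = sg_config()) {
  stopifnot(inherits(config, "sg_config"))
  if (inherits(spectra, "spectra_dataset")) {
    out <- spectra
    out$X <- savitzky_golay_derivative(spectra$X, config)
    return(out)
  }
  X <- as_numeric_matrix(spectra, "spectra")
  m <- ncol(X)
  w <- config$window_length
  h <- (w - 1L) %/% 2L
  if (m < w) {
    stop(sprintf("window_length (%d) exceeds the number of variables (%d)", w, m),
         call. = FALSE)
  }
  out <- matrix(0, nrow(X), m, dimnames = dimnames(X))
  # interior: one coefficient vector, applied by shifted column sums
  c_int <- sg_coefficients((-h):h, config$poly_order, config$deriv_order)
  cols <- (h + 1L):(m - h)
  for (i in seq_len(w)) {
    out[, cols] <- out[, cols] + c_int[i] * X[, cols + (i - h - 1L), drop = FALSE]
  }
  # edges: truncated one-sided windows
  for (j in seq_len(h)) {
    span <- 1L:(j + h)
    cj <- sg_coefficients(span - j, config$poly_order, config$deriv_order)
    out[, j] <- X[, span, drop = FALSE] %*% cj
    span_r <- (m - j - h + 1L):m
    cr <- sg_coefficients(span_r - (m - j + 1L), config$poly_order, config$deriv_order)
    out[, m - j + 1L] <- X[, span_r, drop = FALSE] %*% cr
  }
  out
}

#' Fit centering/scaling state for predictors and response
#'
#' @param X numeric matrix (N x M).
#' @param y optional response vector.
#' @param scale_variance when `TRUE`, columns are also scaled to unit
#'   standard deviation; zero-variance columns keep scale 1 (never divide
#'   by zero). Default `FALSE`: mean-centering only, the footing on which
#'   all weighting/selection methods in this package are compared (unit
#'   variance autoscaling applied after variable weighting would cancel the
#'   weights exactly).
#' @return an object of class `scaling_state` with `column_means`,
#'   `column_scales`, `response_mean`, `response_scale`.
#' @export
fit_scaling <- function(X, y = NULL, scale_variance = FALSE) {
  X <- as_numeric_matrix(X)
  if (nrow(X) < 2L) stop("need at least 2 samples to fit scaling", call. = FALSE)
  mu <- colMeans(X)
  if (scale_variance) {
    s <- apply(X, 2, stats::sd)
    s[!is.finite(s) | s < .Machine$double.eps^0.5 * pmax(abs(mu), 1)] <- 1
  } else {
    s <- rep(1, ncol(X))
  }
  ym <- 0; ys <- 1
  if (!is.null(y)) {
    y <- as.numeric(y)
    ym <- mean(y)
    if (scale_variance) {
      ys <- stats::sd(y)
      if (!is.finite(ys) || ys < .Machine$double.eps^0.5 * max(abs(ym), 1)) ys <- 1
    }
  }
  structure(list(column_means = mu, column_scales = s,
                 response_mean = ym, response_scale = ys),
            class = "scaling_state")
}

#' Apply fitted scaling to data
#'
#' @param state a [fit_scaling()] result.
#' @param X matrix to transform (columns matching the fitted state).
#' @param y optional response vector to transform.
#' @return `X` transformed, or `list(X, y)` when `y` is supplied.
#' @export
apply_scaling <- function(state, X, y = NULL) {
  stopifnot(inherits(state, "scaling_state"))
  X <- as_numeric_matrix(X)
  if (ncol(X) != length(state$column_means)) {
    stop("column count does not match the fitted scaling state", call. = FALSE)
  }
  Xs <- sweep(sweep(X, 2, state$column_means), 2, state$column_scales, `/`)
  if (is.null(y)) return(Xs)
  list(X = Xs, y = (as.numeric(y) - state$response_mean) / state$response_scale)
}

#' Invert fitted scaling
#'
#' @inheritParams apply_scaling
#' @return the data mapped back to the original scale.
#' @export
invert_scaling <- function(state, X = NULL, y = NULL) {
  stopifnot(inherits(state, "scaling_state"))
  out <- list()
  if (!is.null(X)) {
    X <- as_numeric_matrix(X)
    out$X <- sweep(sweep(X, 2, state$column_scales, `*`), 2, state$column_means, `+`)
  }
  if (!is.null(y)) out$y <- as.numeric(y) * state$response_scale + state$response_mean
  if (length(out) == 1L) out[[1L]] else out
}
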