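#' PLS regression by NIPALS
#'
#' Fits a single-response partial least squares model with `ncomp` latent
#' variables by the NIPALS algorithm. Data are mean-centered internally
#' (optionally autoscaled); each weight vector is computed in closed form as
#' the normalized covariance direction `w_k = X'y / ||X'y||` — the dominant
#' eigenvector of the rank-one matrix `X'y y'X` — then scores
#' `t_k = X w_k`, loadings `p_k = X't_k / t_k't_k`, response loadings
#' `b_k = y't_k / t_k't_k`, and deflation `X <- X - t_k p_k'`,
#' `y <- y - b_k t_k`. Weight signs are flipped so the largest-magnitude
#' entry of each `w_k` is positive, making output reproducible across
#' platforms. If the residual covariance vanishes before `ncomp` components
#' the fit stops early with a warning.
#'
#' The fitted model also carries the multiple-linear-regression form
#' `beta_pls = W (P'W)^{-1} b` so that predictions can be computed as a
#' single dot product per sample.
#'
#' @param X numeric matrix (N x M) of predictors, or a [spectra_dataset()]
#'   (in which case `y` is taken from it).
#' @param y numeric response vector of length N.
#' @param ncomp number of latent variables K, `1 <= K <= min(N-1, M)`.
#' @param scale_variance autoscale columns to unit variance (default FALSE;
#'   centering only).
#' @return an object of class `pls_model`: `weights` (W, M x K),
#'   `x_loadings` (P, M x K), `scores` (T, N x K), `y_loadings` (b, length
#'   K), `ncomp`, `beta` (centered-space coefficients), `scaling`
#'   (a `scaling_state`), `x_residual` (E), `y_residual` (f), `fitted`.
#' @examples
#' X <- matrix(rnorm(100), 20, 5)
#' y <- X[, 1] * 3 + rnorm(20, sd = 0.01)
#' fit <- fit_pls(X, y, ncomp = 2)
#' head(predict(fit, X))
#' @export
fit_pls <- function(X, y = NULL, ncomp, scale_variance = FALSE) {
  if (inherits(X, "spectra_dataset")) {
    if (is.null(y)) y <- X$y
    X <- X$X
  }
  X <- as_numeric_matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); m <- ncol(X)
  if (length(y) != n) stop("length(y) must equal nrow(X)", call. = FALSE)
  check_scalar(ncomp, "ncomp", lower = 1, upper = min(n - 1, m), integer = TRUE)
  scaling <- fit_scaling(X, y, scale_variance = scale_variance)
  sc <- apply_scaling(scaling, X, y)
  Xk <- sc$X; yk <- sc$y
  ref <- sqrt(sum(crossprod(Xk, yk)^2))
  W <- matrix(0, m, ncomp); P <- matrix(0, m, ncomp)
  Tm <- matrix(0, n, ncomp); b <- numeric(ncomp)
  k_fit <- 0L
  for (k in seq_len(ncomp)) {
    cv <- crossprod(Xk, yk)  # X_{k-1}' y_{k-1}
    nrm <- sqrt(sum(cv^2))
    if (!is.finite(nrm) || nrm <= max(ref, 1) * 1e-14) {
      if (k > 1L) {
        warning(sprintf("NIPALS stopped early at %d component(s): residual covariance is zero", k - 1L),
                call. = FALSE)
      }
      break
    }
    w <- cv / nrm
    imax <- which.max(abs(w))
    if (w[imax] < 0) w <- -w
    t_k <- drop(Xk %*% w)
    tt <- sum(t_k^2)
    if (tt <= 0) {
      warning(sprintf("NIPALS stopped early at %d component(s): zero score", k - 1L),
              call. = FALSE)
      break
    }
    p <- drop(crossprod(Xk, t_k)) / tt
    bk <- sum(yk * t_k) / tt
    Xk <- Xk - tcrossprod(t_k, p)
    yk <- yk - bk * t_k
    W[, k] <- w; P[, k] <- p; Tm[, k] <- t_k; b[k] <- bk
    k_fit <- k
  }
  if (k_fit == 0L) stop("no PLS component could be extracted: X'y is zero", call. = FALSE)
  W <- W[, seq_len(k_fit), drop = FALSE]
  P <- P[, seq_len(k_fit), drop = FALSE]
  Tm <- Tm[, seq_len(k_fit), drop = FALSE]
  b <- b[seq_len(k_fit)]
  beta <- drop(W %*% solve(crossprod(P, W), b))
  fitted <- drop(Tm %*% b) * scaling$response_scale + scaling$response_mean
  structure(list(weights = W, x_loadings = P, scores = Tm, y_loadings = b,
                 ncomp = k_fit, beta = beta, scaling = scaling,
                 x_residual = Xk, y_residual = yk, fitted = fitted,
                 var_labels = colnames(X)),
            class = "pls_model")
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("pls_model: %d latent variable(s), %d predictors, %d samples\n",
              x$ncomp, nrow(x$weights), nrow(x$scores)))
  invisible(x)
}

# Centered-space coefficient vector using only the first k components.
pls_beta_k <- function(model, k) {
  W <- model$weights[, seq_len(k), drop = FALSE]
  P <- model$x_loadings[, seq_len(k), drop = FALSE]
  drop(W %*% solve(crossprod(P, W), model$y_loadings[seq_len(k)]))
}

#' Predict from a fitted PLS model
#'
#' @param object a [fit_pls()] model.
#' @param newdata numeric matrix with the model's M columns, or a
#'   [spectra_dataset()].
#' @param ncomp number of components to use (default: all fitted).
#' @param ... unused.
#' @return numeric vector of predictions on the response scale.
#' @export
predict.pls_model <- function(object, newdata, ncomp = object$ncomp, ...) {
  if (inherits(newdata, "spectra_dataset")) newdata <- newdata$X
  newdata <- as_numeric_matrix(newdata, "newdata")
  if (ncol(newdata) != nrow(object$weights)) {
    stop("newdata has the wrong number of columns", call. = FALSE)
  }
  check_scalar(ncomp, "ncomp", lower = 1, upper = object$ncomp, integer = TRUE)
  beta <- if (ncomp == object$ncomp) object$beta else pls_beta_k(object, ncomp)
  Xs <- apply_scaling(object$scaling, newdata)
  drop(Xs %*% beta) * object$scaling$response_scale + object$scaling$response_mean
}

#' Coefficients of a PLS model in MLR form
#'
#' Returns the model expressed as ordinary regression coefficients on the
#' original predictor scale, with the intercept as attribute.
#'
#' @param object a `pls_model`.
#' @param ... unused.
#' @return numeric vector of length M (attribute `"intercept"`).
#' @export
coef.pls_model <- function(object, ...) {
  s <- object$scaling
  beta <- object$beta / s$column_scales * s$response_scale
  structure(beta, intercept = s$response_mean - sum(beta * s$column_means),
            names = object$var_labels)
}

#' Cross-validated choice of the number of latent variables
#'
#' K-fold cross-validation with seeded random fold assignment; centering
#' (and optional scaling) is refit inside each training fold. Returns the K
#' minimizing the root-mean-square cross-validation error (minimum rule, no
#' one-standard-error rule).
#'
#' @param X predictor matrix or [spectra_dataset()].
#' @param y response (taken from the dataset when omitted).
#' @param K_max largest number of components to consider; default
#'   `min(40, N - ceiling(N/folds) - 1, M)`.
#' @param folds number of folds (>= 2).
#' @param seed integer seed for the fold assignment.
#' @param scale_variance passed to [fit_pls()].
#' @return the selected integer K, with attributes `rmsecv` (the error
#'   curve) and `folds`.
#' @export
select_components_cv <- function(X, y = NULL, K_max = NULL, folds = 10L,
                                 seed = 1L, scale_variance = FALSE) {
  if (inherits(X, "spectra_dataset")) {
    if (is.null(y)) y <- X$y
    X <- X$X
  }
  X <- as_numeric_matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  check_scalar(folds, "folds", lower = 2, upper = n, integer = TRUE)
  cap <- min(n - ceiling(n / folds) - 1L, ncol(X))
  if (is.null(K_max)) K_max <- min(40L, cap)
  check_scalar(K_max, "K_max", lower = 1, upper = cap, integer = TRUE)
  assign_fold <- with_local_seed(seed, sample(rep(seq_len(folds), length.out = n)))
  sse <- rep(0, K_max)
  k_eff <- K_max
  for (f in seq_len(folds)) {
    te <- assign_fold == f
    fit <- suppressWarnings(fit_pls(X[!te, , drop = FALSE], y[!te],
                                    ncomp = min(K_max, sum(!te) - 1L),
                                    scale_variance = scale_variance))
    k_eff <- min(k_eff, fit$ncomp)
    Xs <- apply_scaling(fit$scaling, X[te, , drop = FALSE])
    for (k in seq_len(fit$ncomp)) {
      pred <- drop(Xs %*% pls_beta_k(fit, k)) * fit$scaling$response_scale +
        fit$scaling$response_mean
      sse[k] <- sse[k] + sum((y[te] - pred)^2)
    }
  }
  rmsecv <- sqrt(sse[seq_len(k_eff)] / n)
  k_best <- which.min(rmsecv)
  structure(as.integer(k_best), rmsecv = rmsecv, folds = folds)
}

#' Variable influence on projection (VIP) scores
#'
#' `V_j = sqrt(M * sum_k[w_jk^2 b_k^2 (t_k't_k) / ||w_k||^2] /
#' sum_k[b_k^2 (t_k't_k)])`. The squared scores average to 1 over
#' variables, so `eta` thresholds near 1 separate above-average from
#' below-average contributors.
#'
#' @param model a fitted `pls_model`.
#' @param eta selection threshold (> 0); variables with `V_j > eta` form
#'   the `selected` element.
#' @return object of class `vip_scores`: `scores` (length M), `eta`,
#'   `selected` (integer indices).
#' @export
vip_scores <- function(model, eta = 1) {
  stopifnot(inherits(model, "pls_model"))
  check_scalar(eta, "eta", lower = 0, open_lower = TRUE)
  W <- model$weights
  tt <- colSums(model$scores^2)
  expl <- model$y_loadings^2 * tt
  if (sum(expl) <= 0) stop("all response loadings are zero: VIP undefined", call. = FALSE)
  wnorm2 <- colSums(W^2)
  m <- nrow(W)
  v2 <- m * drop((W^2 %*% (expl / wnorm2))) / sum(expl)
  structure(list(scores = sqrt(v2), eta = eta, selected = which(sqrt(v2) > eta)),
            class = "vip_scores")
}

#' PLS-Beta variable selection
#'
#' Ranks variables by descending `|beta_pls|` (the MLR-form coefficients of
#' the fitted model in centered space) and greedily retains the shortest
#' prefix whose coefficient-norm ratio `||beta_select|| / ||beta_pls||`
#' reaches the threshold `nu`.
#'
#' @param model a fitted `pls_model`.
#' @param nu norm-ratio threshold in (0, 1].
#' @return object of class `pls_beta_selection`: `order` (indices by
#'   descending magnitude), `nu`, `selected` (sorted indices),
#'   `achieved_ratio`.
#' @export
pls_beta_select <- function(model, nu) {
  stopifnot(inherits(model, "pls_model"))
  check_scalar(nu, "nu", lower = 0, upper = 1, open_lower = TRUE)
  beta <- model$beta
  total <- sqrt(sum(beta^2))
  if (total == 0) stop("beta_pls is zero: nothing to select", call. = FALSE)
  ord <- order(-abs(beta), seq_along(beta))
  ratio <- sqrt(cumsum(beta[ord]^2)) / total
  n_sel <- which(ratio >= nu - 1e-15)[1L]
  structure(list(order = ord, nu = nu,
                 selected = sort(ord[seq_len(n_sel)]),
                 achieved_ratio = ratio[n_sel]),
            class = "pls_beta_selection")
}

#' Export a fitted PLS model to JSON
#'
#' Serializes all matrices, the scaling state, K, and optional provenance
#' metadata (method name, NC gamma, etc.) so a model can be archived or
#' reloaded with [read_pls_json()].
#'
#' @param model a `pls_model`.
#' @param file output path.
#' @param metadata optional named list stored verbatim.
#' @return invisibly, `model`.
#' @export
write_pls_json <- function(model, file, metadata = NULL) {
  stopifnot(inherits(model, "pls_model"))
  payload <- list(
    ncomp = model$ncomp,
    weights = model$weights, x_loadings = model$x_loadings,
    y_loadings = model$y_loadings, beta = model$beta,
    scaling = unclass(model$scaling),
    var_labels = model$var_labels,
    metadata = metadata)
  jsonlite::write_json(payload, file, digits = NA, auto_unbox = TRUE)
  invisible(model)
}

#' Read a PLS model written by [write_pls_json()]
#'
#' The reloaded model supports prediction; training scores and residuals
#' are not serialized.
#'
#' @param file path to the JSON file.
#' @return a `pls_model` (without `scores`, `x_residual`, `y_residual`).
#' @export
read_pls_json <- function(file) {
  p <- jsonlite::read_json(file, simplifyVector = TRUE)
  scaling <- structure(p$scaling, class = "scaling_state")
  structure(list(weights = as.matrix(p$weights), x_loadings = as.matrix(p$x_loadings),
                 y_loadings = as.numeric(p$y_loadings), ncomp = as.integer(p$ncomp),
                 beta = as.numeric(p$beta), scaling = scaling,
                 scores = matrix(numeric(0), 0, p$ncomp),
                 var_labels = p$var_labels, metadata = p$metadata),
            class = "pls_model")
}
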