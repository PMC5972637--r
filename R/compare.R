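#' RMSE and coefficient of determination
#'
#' `RMSE = sqrt(mean((y_true - y_pred)^2))`;
#' `R2 = 1 - SSE / SST` with SST about the mean of `y_true`.
#'
#' @param y_true observed values (length >= 2, non-constant for R2).
#' @param y_pred predicted values of the same length.
#' @return named numeric vector `c(rmse = , r2 = )`.
#' @export
rmse_r2 <- function(y_true, y_pred) {
  y_true <- as.numeric(y_true); y_pred <- as.numeric(y_pred)
  if (length(y_true) < 2L || length(y_true) != length(y_pred)) {
    stop("y_true and y_pred must have equal length >= 2", call. = FALSE)
  }
  sst <- sum((y_true - mean(y_true))^2)
  if (sst == 0) stop("y_true is constant: R2 undefined", call. = FALSE)
  sse <- sum((y_true - y_pred)^2)
  c(rmse = sqrt(mean((y_true - y_pred)^2)), r2 = 1 - sse / sst)
}

#' Published parameter grids for the comparison harness
#'
#' The grid of tuning values tried for each method in the reference
#' protocol: PLS-Beta's norm-ratio thresholds, VIP thresholds, lasso
#' penalties, stepwise p-value thresholds, and the NCSC grids (J, P, D, and
#' the group-lasso lambda) at the fixed NC threshold gamma = 0.99. NCVW has
#' no grid: gamma = 0.99 is its single, fixed parameter.
#'
#' @return named list of per-method parameter grids.
#' @export
default_parameter_grids <- function() {
  list(
    pls_all  = list(),
    pls_beta = list(nu = c(0.70, 0.75, 0.80, 0.85, 0.90, 0.95)),
    vip      = list(eta = c(0.6, 0.7, 0.8, 0.9, 1.0, 1.1)),
    lasso    = list(lambda = c(0.1, 0.2, 0.4, 0.5, 0.8, 1.0)),
    stepwise = list(p_threshold = c(0.005, 0.05, 0.08, 0.1, 0.12, 0.15)),
    ncsc_vs  = list(gamma = 0.99, J = 5:10, P = 9:11, D = 2:3),
    ncsc_gl  = list(gamma = 0.99, J = 5:10, lambda = c(20, 25)),
    ncvw     = list(gamma = 0.99),
    ccvw     = list()
  )
}

ncvw_methods <- c("pls_all", "pls_beta", "vip", "lasso", "stepwise",
                  "ncsc_vs", "ncsc_gl", "ncvw", "ccvw")

#' Configuration of a single comparison-harness run
#'
#' Validates that the supplied parameters belong to the chosen method and
#' that every required grid is present and non-empty. The parameter-economy
#' contract of NCVW is enforced here: `run_config("ncvw")` is complete with
#' no parameters at all (`gamma` defaults to 0.99), whereas `"ncsc_vs"`
#' requires its full `J`, `P`, `D` grids and `"ncsc_gl"` requires `J` and
#' `lambda` — there are no published defaults that make those methods
#' tuning-free.
#'
#' @param method one of `"pls_all"`, `"pls_beta"`, `"vip"`, `"lasso"`,
#'   `"stepwise"`, `"ncsc_vs"`, `"ncsc_gl"`, `"ncvw"`, `"ccvw"`.
#' @param ... method parameters: `nu` (pls_beta), `eta` (vip), `lambda`
#'   (lasso, ncsc_gl), `p_threshold` (stepwise), `gamma` (NC methods;
#'   default 0.99), `J`, `P`, `D` (NCSC grids). Grid parameters may be
#'   vectors.
#' @param sg an [sg_config()] applied to the spectra before modelling, or
#'   `NULL` for none.
#' @param cv_folds,K_max,seed cross-validation settings shared by all
#'   methods.
#' @param select_by `"train"` (grid point with minimal training RMSE, the
#'   reference protocol) or `"cv"` (minimal cross-validated RMSE of the
#'   final model, a safer optional rule).
#' @return an object of class `run_config`.
#' @export
run_config <- function(method, ..., sg = NULL, cv_folds = 10L, K_max = NULL,
                       seed = 1L, select_by = c("train", "cv")) {
  if (length(method) != 1L || !method %in% ncvw_methods) {
    stop(sprintf("unknown method; expected one of: %s",
                 paste(ncvw_methods, collapse = ", ")), call. = FALSE)
  }
  select_by <- match.arg(select_by)
  params <- list(...)
  allowed <- switch(method,
    pls_all  = character(0),
    pls_beta = "nu",
    vip      = "eta",
    lasso    = "lambda",
    stepwise = "p_threshold",
    ncsc_vs  = c("gamma", "J", "P", "D"),
    ncsc_gl  = c("gamma", "J", "lambda"),
    ncvw     = "gamma",
    ccvw     = character(0))
  extra <- setdiff(names(params), allowed)
  if (length(extra) || (length(params) && is.null(names(params)))) {
    stop(sprintf("parameters not used by method '%s': %s", method,
                 paste(extra, collapse = ", ")), call. = FALSE)
  }
  required <- switch(method,
    pls_beta = "nu", vip = "eta", lasso = "lambda", stepwise = "p_threshold",
    ncsc_vs  = c("J", "P", "D"),
    ncsc_gl  = c("J", "lambda"),
    character(0))
  missing <- setdiff(required, names(params))
  if (length(missing)) {
    stop(sprintf("method '%s' requires parameter grid(s): %s", method,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  empty <- names(params)[lengths(params) == 0L]
  if (length(empty)) {
    stop(sprintf("empty parameter grid(s): %s", paste(empty, collapse = ", ")),
         call. = FALSE)
  }
  if (method %in% c("ncsc_vs", "ncsc_gl", "ncvw") && is.null(params$gamma)) {
    params$gamma <- 0.99
  }
  if (!is.null(params$gamma) && length(params$gamma) != 1L) {
    stop("`gamma` must be a single value", call. = FALSE)
  }
  if (!is.null(sg)) stopifnot(inherits(sg, "sg_config"))
  structure(list(method = method, params = params, sg = sg,
                 cv_folds = as.integer(cv_folds), K_max = K_max,
                 seed = as.integer(seed), select_by = select_by),
            class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  ps <- if (length(x$params)) {
    paste(vapply(names(x$params), function(nm)
      sprintf("%s = {%s}", nm, paste(x$params[[nm]], collapse = ", ")),
      character(1)), collapse = "; ")
  } else "none"
  cat(sprintf("run_config: method %s, parameters: %s\n", x$method, ps))
  invisible(x)
}

# Expand a config's grid into a list of single-value parameter sets.
expand_param_grid <- function(params) {
  if (length(params) == 0L) return(list(list()))
  grid <- do.call(expand.grid, c(params, list(KEEP.OUT.ATTRS = FALSE)))
  lapply(seq_len(nrow(grid)), function(i) as.list(grid[i, , drop = FALSE]))
}

format_params <- function(p) {
  if (length(p) == 0L) return("-")
  paste(sprintf("%s = %g", names(p), unlist(p)), collapse = ", ")
}

# Fit one method at one grid point; returns list(model-ish, n_selected, ncomp)
# where the model supports predict(model, X).
fit_one <- function(train, point, config) {
  cvk <- function(sub) {
    cap <- min(nrow(sub$X) - ceiling(nrow(sub$X) / config$cv_folds) - 1L,
               ncol(sub$X))
    km <- if (is.null(config$K_max)) NULL else min(config$K_max, cap)
    as.integer(select_components_cv(sub, folds = config$cv_folds,
                                    seed = config$seed, K_max = km))
  }
  refit <- function(vars) {
    if (length(vars) == 0L) stop("no variables selected", call. = FALSE)
    sub <- subset_dataset(train, variables = vars)
    model <- suppressWarnings(fit_pls(sub, ncomp = cvk(sub)))
    pred <- function(X) predict(model, X[, vars, drop = FALSE])
    list(predict = pred, n_selected = length(vars), ncomp = model$ncomp,
         vars = vars)
  }
  m <- ncol(train$X)
  switch(config$method,
    pls_all = {
      model <- suppressWarnings(fit_pls(train, ncomp = cvk(train)))
      list(predict = function(X) predict(model, X), n_selected = m,
           ncomp = model$ncomp, vars = seq_len(m))
    },
    pls_beta = {
      full <- fit_one_full_pls(train, config)
      refit(pls_beta_select(full, point$nu)$selected)
    },
    vip = {
      full <- fit_one_full_pls(train, config)
      refit(vip_scores(full, eta = point$eta)$selected)
    },
    lasso = {
      scaling <- fit_scaling(train$X, train$y)
      sc <- apply_scaling(scaling, train$X, train$y)
      fit <- fit_lasso(sc$X, sc$y, point$lambda)
      refit(fit$support)
    },
    stepwise = {
      refit(as.integer(stepwise_select(train, p_threshold = point$p_threshold)))
    },
    ncsc_vs = {
      aff <- nc_cache_affinity(train, gamma = config$params$gamma)
      grouping <- spectral_partition(aff, J = point$J, seed = config$seed)
      fit <- ncsc_vs(train, grouping, P = point$P,
                     D = min(point$D, length(grouping$groups)),
                     cv_folds = config$cv_folds, seed = config$seed,
                     K_max = config$K_max)
      vars <- fit$variables
      list(predict = function(X) predict(fit$model, X[, vars, drop = FALSE]),
           n_selected = length(vars), ncomp = fit$ncomp, vars = vars)
    },
    ncsc_gl = {
      aff <- nc_cache_affinity(train, gamma = config$params$gamma)
      grouping <- spectral_partition(aff, J = point$J, seed = config$seed)
      fit <- ncsc_gl(train, grouping, lambda = point$lambda,
                     cv_folds = config$cv_folds, seed = config$seed,
                     K_max = config$K_max)
      vars <- fit$variables
      list(predict = function(X) predict(fit$model, X[, vars, drop = FALSE]),
           n_selected = length(vars), ncomp = fit$ncomp, vars = vars)
    },
    ncvw = {
      fit <- ncvw_pipeline(train, config = nc_config(config$params$gamma),
                           cv_folds = config$cv_folds, K_max = config$K_max,
                           seed = config$seed)
      list(predict = function(X) predict(fit, X), n_selected = m,
           ncomp = fit$ncomp, vars = seq_len(m), weights = fit$weights)
    },
    ccvw = {
      fit <- ccvw_pipeline(train, cv_folds = config$cv_folds,
                           K_max = config$K_max, seed = config$seed)
      list(predict = function(X) predict(fit, X), n_selected = m,
           ncomp = fit$ncomp, vars = seq_len(m), weights = fit$weights)
    })
}

# Full-spectrum CV'd PLS, cached per call chain via environment memoization.
fit_one_full_pls <- function(train, config) {
  cache <- attr(train, ".full_pls_cache")
  if (!is.null(cache)) return(cache)
  k <- as.integer(select_components_cv(
    train, folds = config$cv_folds, seed = config$seed,
    K_max = clamp_K_max(config$K_max, train, config$cv_folds)))
  suppressWarnings(fit_pls(train, ncomp = k))
}

# Affinity memoization across grid points (J varies, affinity does not).
nc_affinity_cache <- new.env(parent = emptyenv())
nc_cache_affinity <- function(train, gamma) {
  key <- paste(gamma, nrow(train$X), ncol(train$X),
               format(sum(train$X) + sum(train$y), digits = 17))
  if (!is.null(nc_affinity_cache[[key]])) return(nc_affinity_cache[[key]])
  aff <- variable_affinity(train, include_response = FALSE,
                           config = nc_config(gamma))
  nc_affinity_cache[[key]] <- aff
  aff
}

#' Run one method of the comparison protocol
#'
#' Applies any configured Savitzky-Golay pretreatment to both sets, fits
#' the method at every grid point on the training data, picks the grid
#' point with the lowest training RMSE (the reference protocol; or lowest
#' CV RMSE with `select_by = "cv"`), and reports that model's validation
#' RMSE and R-squared.
#'
#' @param train,validation [spectra_dataset()]s sharing the variable axis.
#' @param config a [run_config()].
#' @return one-row `data.frame`: `method`, `n_selected`, `ncomp`,
#'   `parameters`, `rmse_train`, `rmse_validation`, `r2_validation`.
#' @export
run_method <- function(train, validation, config) {
  stopifnot(inherits(train, "spectra_dataset"),
            inherits(validation, "spectra_dataset"),
            inherits(config, "run_config"))
  if (ncol(train$X) != ncol(validation$X)) {
    stop("train and validation must share the variable axis", call. = FALSE)
  }
  if (!is.null(config$sg)) {
    train <- savitzky_golay_derivative(train, config$sg)
    validation <- savitzky_golay_derivative(validation, config$sg)
  }
  if (config$method %in% c("pls_beta", "vip")) {
    attr(train, ".full_pls_cache") <- fit_one_full_pls(train, config)
  }
  grid_params <- config$params
  grid_params$gamma <- NULL  # gamma is fixed, not a grid axis
  points <- expand_param_grid(grid_params)
  best <- NULL
  for (point in points) {
    fit <- tryCatch(fit_one(train, point, config), error = function(e) e)
    if (inherits(fit, "error")) next
    rmse_tr <- rmse_r2(train$y, fit$predict(train$X))[["rmse"]]
    score <- if (config$select_by == "train") rmse_tr else
      cv_score_of_fit(train, fit, config)
    if (is.null(best) || score < best$score) {
      best <- list(fit = fit, point = point, rmse_train = rmse_tr, score = score)
    }
  }
  if (is.null(best)) {
    stop(sprintf("method '%s' failed at every grid point", config$method),
         call. = FALSE)
  }
  val <- rmse_r2(validation$y, best$fit$predict(validation$X))
  shown <- best$point
  if (!is.null(config$params$gamma)) shown <- c(list(gamma = config$params$gamma), shown)
  data.frame(method = config$method,
             n_selected = best$fit$n_selected,
             ncomp = best$fit$ncomp,
             parameters = format_params(shown),
             rmse_train = unname(best$rmse_train),
             rmse_validation = unname(val[["rmse"]]),
             r2_validation = unname(val[["r2"]]),
             stringsAsFactors = FALSE)
}

# Seeded K-fold CV RMSE of the final PLS model refit per fold on the grid
# point's variable set (and weighting, where the method weights). Used only
# under select_by = "cv".
cv_score_of_fit <- function(train, fit, config) {
  sub <- subset_dataset(train, variables = fit$vars)
  if (!is.null(fit$weights)) sub <- apply_weights(sub, fit$weights)
  n <- nrow(sub$X)
  folds <- config$cv_folds
  assign_fold <- with_local_seed(config$seed,
                                 sample(rep(seq_len(folds), length.out = n)))
  sse <- 0
  for (f in seq_len(folds)) {
    te <- assign_fold == f
    model <- suppressWarnings(fit_pls(
      subset_dataset(sub, samples = which(!te)),
      ncomp = min(fit$ncomp, sum(!te) - 1L)))
    pred <- predict(model, sub$X[te, , drop = FALSE])
    sse <- sse + sum((sub$y[te] - pred)^2)
  }
  sqrt(sse / n)
}

#' Run the full method comparison
#'
#' Fits every requested method on the training set with its published
#' parameter grid (see [default_parameter_grids()]), selects each method's
#' grid point by training RMSE, and scores all final models on the same
#' validation set.
#'
#' @param train,validation [spectra_dataset()]s.
#' @param methods character vector of methods (default: all nine).
#' @param grids named list of parameter grids (default:
#'   [default_parameter_grids()]).
#' @param sg optional [sg_config()] pretreatment shared by all methods.
#' @param cv_folds,K_max,seed shared settings.
#' @return `data.frame` with one row per method (see [run_method()]).
#' @export
compare_methods <- function(train, validation, methods = ncvw_methods,
                            grids = default_parameter_grids(), sg = NULL,
                            cv_folds = 10L, K_max = NULL, seed = 1L) {
  rows <- lapply(methods, function(mth) {
    cfg <- do.call(run_config, c(list(method = mth), grids[[mth]],
                                 list(sg = sg, cv_folds = cv_folds,
                                      K_max = K_max, seed = seed)))
    run_method(train, validation, cfg)
  })
  do.call(rbind, rows)
}
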