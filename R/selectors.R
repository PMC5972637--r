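#' Lasso regression by coordinate descent
#'
#' Minimizes `||y - X b||_2^2 + lambda * ||b||_1` (note: the squared-error
#' term is unhalved, so the soft threshold is `lambda / 2`). Supply centered
#' data; no intercept is fit. Coordinate descent iterates until the KKT
#' residual drops below `tol * max(1, lambda)`, so the returned solution
#' carries a verifiable optimality certificate:
#' `2 x_j' r = lambda * sign(b_j)` on the support and `|2 x_j' r| <= lambda`
#' off it.
#'
#' @param X centered predictor matrix.
#' @param y centered response vector.
#' @param lambda penalty >= 0. At `lambda >= 2 * max|X'y|` the solution is
#'   exactly zero; at `lambda = 0` the (full-rank) least-squares solution is
#'   returned.
#' @param tol KKT tolerance (default 1e-8).
#' @param max_iter maximum coordinate-descent sweeps.
#' @return object of class `lasso_fit`: `coefficients`, `lambda`,
#'   `support` (indices of nonzero coefficients), `iterations`,
#'   `kkt_residual`.
#' @export
fit_lasso <- function(X, y, lambda, tol = 1e-8, max_iter = 100000L) {
  X <- as_numeric_matrix(X)
  y <- as.numeric(y)
  check_scalar(lambda, "lambda", lower = 0)
  m <- ncol(X)
  if (lambda == 0) {
    beta <- stats::lm.fit(X, y)$coefficients
    beta[is.na(beta)] <- 0
    return(new_lasso_fit(beta, lambda, X, y))
  }
  cj <- colSums(X^2)
  beta <- numeric(m)
  r <- y
  scale_ref <- max(1, lambda)
  it <- 0L
  repeat {
    it <- it + 1L
    for (j in seq_len(m)) {
      if (cj[j] == 0) next
      z <- sum(X[, j] * r) + cj[j] * beta[j]
      bnew <- soft_threshold(z, lambda / 2) / cj[j]
      if (bnew != beta[j]) {
        r <- r + X[, j] * (beta[j] - bnew)
        beta[j] <- bnew
      }
    }
    g <- 2 * drop(crossprod(X, r))
    viol <- ifelse(beta != 0, abs(g - lambda * sign(beta)),
                   pmax(abs(g) - lambda, 0))
    viol[cj == 0] <- 0
    if (max(viol) <= tol * scale_ref) break
    if (it >= max_iter) {
      stop(sprintf("lasso coordinate descent did not converge in %d sweeps (KKT residual %.3g)",
                   it, max(viol)), call. = FALSE)
    }
  }
  new_lasso_fit(beta, lambda, X, y, iterations = it)
}

new_lasso_fit <- function(beta, lambda, X, y, iterations = 0L) {
  beta <- as.numeric(beta)
  r <- y - drop(X %*% beta)
  g <- 2 * drop(crossprod(X, r))
  viol <- ifelse(beta != 0, abs(g - lambda * sign(beta)), pmax(abs(g) - lambda, 0))
  structure(list(coefficients = beta, lambda = lambda,
                 support = which(beta != 0),
                 objective = sum(r^2) + lambda * sum(abs(beta)),
                 kkt_residual = if (lambda > 0) max(viol) else NA_real_,
                 iterations = iterations),
            class = "lasso_fit")
}

#' Group lasso by block coordinate descent
#'
#' Minimizes `||y - sum_j X_j b_j||_2^2 + lambda * sum_j sqrt(M_j) ||b_j||_2`
#' over non-overlapping variable groups (the square-root group-size factor
#' balances the penalty across unequal group widths). Each block update is
#' exact: a group is zeroed when `2 ||X_j' r_j||_2 <= lambda sqrt(M_j)`
#' (its KKT activation condition), and otherwise its coefficients solve
#' `(X_j'X_j + lambda sqrt(M_j) / (2 ||b_j||) I) b_j = X_j' r_j`, reduced to
#' a one-dimensional root-finding problem in `||b_j||` via the
#' eigendecomposition of `X_j'X_j`. Sweeps continue until every block's KKT
#' residual is below `tol`.
#'
#' @param group_matrices list of centered matrices `X_j` (same row count).
#' @param y centered response.
#' @param lambda penalty >= 0 (`0` gives the joint least-squares solution).
#' @param tol per-block KKT tolerance (default 1e-6).
#' @param max_iter maximum block sweeps.
#' @return object of class `group_lasso_fit`: `group_coefficients` (list),
#'   `coefficients` (concatenated), `selected_groups`, `lambda`,
#'   `objective`, `iterations`, `kkt_residual`.
#' @export
fit_group_lasso <- function(group_matrices, y, lambda, tol = 1e-6,
                            max_iter = 20000L) {
  stopifnot(is.list(group_matrices), length(group_matrices) >= 1L)
  y <- as.numeric(y)
  check_scalar(lambda, "lambda", lower = 0)
  Xs <- lapply(group_matrices, as_numeric_matrix, arg = "group matrix")
  if (any(vapply(Xs, nrow, 1L) != length(y))) {
    stop("all group matrices must have nrow equal to length(y)", call. = FALSE)
  }
  J <- length(Xs)
  mj <- vapply(Xs, ncol, 1L)
  if (lambda == 0) {
    beta_all <- stats::lm.fit(do.call(cbind, Xs), y)$coefficients
    beta_all[is.na(beta_all)] <- 0
    betas <- split(as.numeric(beta_all), rep(seq_len(J), mj))
    return(new_group_lasso_fit(betas, Xs, y, lambda))
  }
  eigs <- lapply(Xs, function(Xj) eigen(crossprod(Xj), symmetric = TRUE))
  dj <- lambda * sqrt(mj) / 2
  betas <- lapply(mj, numeric)
  r <- y
  scale_ref <- max(1, lambda)
  it <- 0L
  repeat {
    it <- it + 1L
    for (j in seq_len(J)) {
      rj <- r + drop(Xs[[j]] %*% betas[[j]])
      g <- drop(crossprod(Xs[[j]], rj))
      if (sqrt(sum(g^2)) * 2 <= lambda * sqrt(mj[j])) {
        bnew <- numeric(mj[j])
      } else {
        bnew <- group_block_solve(eigs[[j]], g, dj[j])
      }
      r <- rj - drop(Xs[[j]] %*% bnew)
      betas[[j]] <- bnew
    }
    worst <- group_kkt_residual(betas, Xs, r, lambda, mj)
    if (worst <= tol * scale_ref) break
    if (it >= max_iter) {
      stop(sprintf("group lasso did not converge in %d sweeps (KKT residual %.3g)",
                   it, worst), call. = FALSE)
    }
  }
  new_group_lasso_fit(betas, Xs, y, lambda, iterations = it)
}

# Exact block minimizer of ||r - X b||^2 + 2 d ||b|| given g = X'r and the
# eigendecomposition of X'X; reduces to a scalar fixed point in s = ||b||.
group_block_solve <- function(eig, g, d) {
  lam <- pmax(eig$values, 0)
  h <- drop(crossprod(eig$vectors, g))
  null_sp <- lam <= max(lam) * 1e-12
  h[null_sp] <- 0          # X'r lies in range(X'X); clean numerical dust
  phi <- function(s) sqrt(sum((h * s / (lam * s + d))^2)) - s
  pos <- lam > 0
  s_hi <- sqrt(sum((h[pos] / lam[pos])^2)) + 1
  s_lo <- s_hi * 1e-14
  if (phi(s_lo) <= 0) return(numeric(length(g)))
  s <- stats::uniroot(phi, c(s_lo, s_hi), tol = 1e-13)$root
  drop(eig$vectors %*% (h * s / (lam * s + d)))
}

group_kkt_residual <- function(betas, Xs, r, lambda, mj) {
  worst <- 0
  for (j in seq_along(Xs)) {
    g <- 2 * drop(crossprod(Xs[[j]], r))
    nb <- sqrt(sum(betas[[j]]^2))
    res <- if (nb > 0) {
      sqrt(sum((g - lambda * sqrt(mj[j]) * betas[[j]] / nb)^2))
    } else {
      max(sqrt(sum(g^2)) - lambda * sqrt(mj[j]), 0)
    }
    worst <- max(worst, res)
  }
  worst
}

new_group_lasso_fit <- function(betas, Xs, y, lambda, iterations = 0L) {
  mj <- vapply(Xs, ncol, 1L)
  pred <- Reduce(`+`, Map(function(Xj, bj) drop(Xj %*% bj), Xs, betas))
  r <- y - pred
  obj <- sum(r^2) + lambda * sum(sqrt(mj) * vapply(betas, function(b) sqrt(sum(b^2)), 1))
  structure(list(group_coefficients = betas,
                 coefficients = unlist(betas, use.names = FALSE),
                 selected_groups = which(vapply(betas, function(b) any(b != 0), TRUE)),
                 lambda = lambda, objective = obj,
                 kkt_residual = if (lambda > 0) group_kkt_residual(betas, Xs, r, lambda, mj) else NA_real_,
                 iterations = iterations),
            class = "group_lasso_fit")
}

#' Stepwise variable selection by partial F-tests
#'
#' Classical stepwise regression on an intercept-plus-predictors linear
#' model: at each step the candidate whose partial F-test (equivalently
#' t-test) p-value is smallest is added if it is below `p_threshold`; in
#' bidirectional mode any included variable whose p-value rises above the
#' threshold is then dropped. Iterates to a fixed point. Rank-deficient
#' candidates are skipped.
#'
#' @param X predictor matrix (N x M) or [spectra_dataset()].
#' @param y response vector.
#' @param p_threshold entry/stay p-value threshold in (0, 1).
#' @param direction `"bidirectional"` (default) or `"forward"`.
#' @param max_steps safety cap on add/drop steps.
#' @return sorted integer vector of selected column indices (possibly
#'   empty), with attribute `"p_values"` giving the final model's partial
#'   F p-values.
#' @export
stepwise_select <- function(X, y = NULL, p_threshold = 0.05,
                            direction = c("bidirectional", "forward"),
                            max_steps = NULL) {
  if (inherits(X, "spectra_dataset")) {
    if (is.null(y)) y <- X$y
    X <- X$X
  }
  X <- as_numeric_matrix(X)
  y <- as.numeric(y)
  check_scalar(p_threshold, "p_threshold", lower = 0, upper = 1, open_lower = TRUE)
  if (p_threshold >= 1) stop("`p_threshold` must be < 1", call. = FALSE)
  direction <- match.arg(direction)
  n <- nrow(X); m <- ncol(X)
  if (is.null(max_steps)) max_steps <- 10L * m + 50L
  df <- as.data.frame(X)
  names(df) <- paste0("V", seq_len(m))
  df$.y <- y
  selected <- integer(0)
  steps <- 0L
  repeat {
    changed <- FALSE
    steps <- steps + 1L
    if (steps > max_steps) break
    remaining <- setdiff(seq_len(m), selected)
    # forward step: needs residual df after adding one more term
    if (length(remaining) > 0 && n - length(selected) - 2L >= 1L) {
      fml <- stats::as.formula(paste(".y ~", if (length(selected))
        paste(names(df)[selected], collapse = " + ") else "1"))
      fit <- stats::lm(fml, data = df)
      scope <- stats::as.formula(paste("~ . +", paste(names(df)[remaining], collapse = " + ")))
      a1 <- tryCatch(stats::add1(fit, scope = scope, test = "F"),
                     error = function(e) NULL)
      if (!is.null(a1)) {
        pv <- a1[["Pr(>F)"]]
        names(pv) <- rownames(a1)
        pv <- pv[!is.na(pv)]
        if (length(pv) && min(pv) < p_threshold) {
          add_var <- names(pv)[which.min(pv)]
          selected <- c(selected, match(add_var, names(df)))
          changed <- TRUE
        }
      }
    }
    # backward step
    if (direction == "bidirectional" && length(selected) > 0) {
      fml <- stats::as.formula(paste(".y ~", paste(names(df)[selected], collapse = " + ")))
      fit <- stats::lm(fml, data = df)
      d1 <- stats::drop1(fit, test = "F")
      pv <- d1[["Pr(>F)"]]
      names(pv) <- rownames(d1)
      pv <- pv[!is.na(pv)]
      worst <- pv[pv > p_threshold]
      if (length(worst)) {
        drop_var <- names(worst)[which.max(worst)]
        selected <- setdiff(selected, match(drop_var, names(df)))
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  selected <- sort(selected)
  pvals <- NULL
  if (length(selected)) {
    fml <- stats::as.formula(paste(".y ~", paste(names(df)[selected], collapse = " + ")))
    d1 <- stats::drop1(stats::lm(fml, data = df), test = "F")
    pvals <- stats::setNames(d1[["Pr(>F)"]][-1L], rownames(d1)[-1L])
  }
  structure(selected, p_values = pvals)
}

#' NCSC-based variable selection (contribution ranking)
#'
#' Fits a `P`-component PLS model to each variable group, scores each
#' group's contribution to the response, keeps the top `D` groups, and fits
#' the final cross-validated PLS model on the union of their variables.
#' The default contribution index is the coefficient of determination of
#' the per-group fit, `C_j = 1 - ||y - yhat_j||^2 / ||y||^2` on centered
#' `y`; `contribution = "literal"` uses `1 - ||yhat_j||^2 / ||y||^2`
#' instead (ranking by explained-energy complement). Ties rank the lower
#' group index first.
#'
#' @param dataset a [spectra_dataset()] with response.
#' @param grouping a [spectral_partition()] result over the dataset's
#'   variables.
#' @param P latent variables for the per-group models (capped per group at
#'   `min(P, M_j, N-1)`).
#' @param D number of groups to keep (<= number of groups).
#' @param contribution `"r2"` (default) or `"literal"`.
#' @param cv_folds,seed,K_max settings for the final cross-validated fit.
#' @return object of class `ncsc_vs_fit`: `contributions`,
#'   `selected_groups`, `variables` (union of selected indices), `model`
#'   (final `pls_model`), `ncomp`.
#' @export
ncsc_vs <- function(dataset, grouping, P, D, contribution = c("r2", "literal"),
                    cv_folds = 10L, seed = 1L, K_max = NULL) {
  stopifnot(inherits(dataset, "spectra_dataset"),
            inherits(grouping, "variable_grouping"))
  contribution <- match.arg(contribution)
  J <- length(grouping$groups)
  check_scalar(P, "P", lower = 1, integer = TRUE)
  check_scalar(D, "D", lower = 1, upper = J, integer = TRUE)
  Xjs <- group_matrices(dataset, grouping)
  y <- dataset$y
  yc <- y - mean(y)
  ss_y <- sum(yc^2)
  n <- nrow(dataset$X)
  contrib <- vapply(Xjs, function(Xj) {
    pj <- min(P, ncol(Xj), n - 1L)
    fit <- suppressWarnings(fit_pls(Xj, y, ncomp = pj))
    yhat_c <- fit$fitted - mean(y)
    if (contribution == "r2") {
      1 - sum((yc - yhat_c)^2) / ss_y
    } else {
      1 - sum(yhat_c^2) / ss_y
    }
  }, 1)
  ord <- order(-contrib, seq_len(J))
  sel_groups <- sort(ord[seq_len(D)])
  vars <- sort(unlist(grouping$groups[sel_groups]))
  if (length(vars) == 0L) stop("selected groups contain no variables", call. = FALSE)
  sub <- subset_dataset(dataset, variables = vars)
  k <- select_components_cv(sub, folds = cv_folds, seed = seed,
                            K_max = clamp_K_max(K_max, sub, cv_folds))
  model <- suppressWarnings(fit_pls(sub, ncomp = as.integer(k)))
  structure(list(contributions = contrib, selected_groups = sel_groups,
                 variables = vars, model = model, ncomp = model$ncomp,
                 P = P, D = D),
            class = "ncsc_vs_fit")
}

#' NCSC group lasso (NCSC-GL) variable-group selection
#'
#' Applies the group lasso to the variable groups produced by NC spectral
#' clustering (data centered internally) and returns the selected groups
#' and variables, plus a final cross-validated PLS model on the selected
#' variables.
#'
#' @inheritParams ncsc_vs
#' @param lambda group-lasso penalty.
#' @return object of class `ncsc_gl_fit`: `fit` (the `group_lasso_fit`),
#'   `selected_groups`, `variables`, `model`, `ncomp`.
#' @export
ncsc_gl <- function(dataset, grouping, lambda, cv_folds = 10L, seed = 1L,
                    K_max = NULL) {
  stopifnot(inherits(dataset, "spectra_dataset"),
            inherits(grouping, "variable_grouping"))
  scaling <- fit_scaling(dataset$X, dataset$y)
  sc <- apply_scaling(scaling, dataset$X, dataset$y)
  Xjs <- lapply(grouping$groups, function(g) sc$X[, g, drop = FALSE])
  gl <- fit_group_lasso(Xjs, sc$y, lambda)
  sel_groups <- gl$selected_groups
  if (length(sel_groups) == 0L) {
    stop("group lasso selected no groups at this lambda", call. = FALSE)
  }
  vars <- sort(unlist(grouping$groups[sel_groups]))
  sub <- subset_dataset(dataset, variables = vars)
  k <- select_components_cv(sub, folds = cv_folds, seed = seed,
                            K_max = clamp_K_max(K_max, sub, cv_folds))
  model <- suppressWarnings(fit_pls(sub, ncomp = as.integer(k)))
  structure(list(fit = gl, selected_groups = sel_groups, variables = vars,
                 model = model, ncomp = model$ncomp, lambda = lambda),
            class = "ncsc_gl_fit")
}
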