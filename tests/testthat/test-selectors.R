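test_that("lasso reduces to least squares at lambda 0 and to zero above the threshold", {
  p <- random_regression(40, 6, seed = 1)
  f0 <- fit_lasso(p$X, p$y, 0)
  ols <- stats::lm.fit(p$X, p$y)$coefficients
  expect_equal(f0$coefficients, unname(ols), tolerance = 1e-6)
  lam_max <- 2 * max(abs(crossprod(p$X, p$y)))
  fmax <- fit_lasso(p$X, p$y, lam_max * 1.001)
  expect_equal(fmax$coefficients, rep(0, 6))
  expect_length(fmax$support, 0)
})

test_that("lasso matches soft thresholding on orthonormal designs", {
  set.seed(4)
  Q <- qr.Q(qr(matrix(rnorm(50 * 5), 50, 5)))
  y <- rnorm(50)
  lam <- 0.8
  fit <- fit_lasso(Q, y, lam)
  z <- drop(crossprod(Q, y))
  expect_equal(fit$coefficients, sign(z) * pmax(abs(z) - lam / 2, 0),
               tolerance = 1e-8)
})

test_that("lasso solutions agree with glmnet and carry KKT certificates", {
  for (s in 1:5) {
    p <- random_regression(60, 10, seed = 200 + s)
    lam <- 0.5 + s / 10
    fit <- fit_lasso(p$X, p$y, lam)
    expect_lt(fit$kkt_residual, 1e-5)
    # glmnet minimizes (1/2n)||y-Xb||^2 + lambda_g ||b||_1
    g <- glmnet::glmnet(p$X, p$y, lambda = lam / (2 * length(p$y)),
                        standardize = FALSE, intercept = FALSE,
                        thresh = 1e-14)
    expect_equal(fit$coefficients, as.numeric(g$beta), tolerance = 1e-5)
    # objective no worse than at 0 or at the OLS point
    obj <- function(b) sum((p$y - p$X %*% b)^2) + lam * sum(abs(b))
    expect_lte(fit$objective, obj(rep(0, 10)) + 1e-10)
    expect_lte(fit$objective, obj(stats::lm.fit(p$X, p$y)$coefficients) + 1e-10)
  }
})

test_that("group lasso satisfies block KKT conditions and its null threshold", {
  for (s in 1:5) {
    p <- random_regression(50, 9, seed = 300 + s)
    Xs <- list(p$X[, 1:4], p$X[, 5:6], p$X[, 7:9])
    lam <- 2 + s
    fit <- fit_group_lasso(Xs, p$y, lam)
    r <- p$y - Reduce(`+`, Map(`%*%`, Xs, fit$group_coefficients))
    for (j in 1:3) {
      g <- 2 * drop(crossprod(Xs[[j]], r))
      bj <- fit$group_coefficients[[j]]
      mj <- ncol(Xs[[j]])
      if (any(bj != 0)) {
        expect_lt(max(abs(g - lam * sqrt(mj) * bj / sqrt(sum(bj^2)))), 1e-5)
      } else {
        expect_lte(sqrt(sum(g^2)), lam * sqrt(mj) + 1e-5)
      }
    }
    expect_lte(fit$objective,
               sum(p$y^2) + 1e-10)  # objective at beta = 0
  }
  # all groups zero above the activation threshold
  p <- random_regression(40, 6, seed = 77)
  Xs <- list(p$X[, 1:3], p$X[, 4:6])
  lam_max <- max(vapply(Xs, function(Xj)
    2 * sqrt(sum(crossprod(Xj, p$y)^2)) / sqrt(ncol(Xj)), 1))
  fit0 <- fit_group_lasso(Xs, p$y, lam_max * 1.001)
  expect_length(fit0$selected_groups, 0)
})

test_that("group lasso with singleton groups equals the lasso", {
  p <- random_regression(45, 7, seed = 55)
  lam <- 1.3
  gl <- fit_group_lasso(lapply(1:7, function(j) p$X[, j, drop = FALSE]), p$y, lam,
                        tol = 1e-9)
  la <- fit_lasso(p$X, p$y, lam, tol = 1e-10)
  expect_equal(gl$coefficients, la$coefficients, tolerance = 1e-6)
  # lambda = 0 reduces to the joint least-squares solution
  gl0 <- fit_group_lasso(list(p$X[, 1:3], p$X[, 4:7]), p$y, 0)
  expect_equal(gl0$coefficients,
               unname(stats::lm.fit(p$X, p$y)$coefficients), tolerance = 1e-8)
})

test_that("stepwise selects a dominant signal and matches the partial-F oracle", {
  set.seed(10)
  X <- matrix(rnorm(80 * 6), 80, 6)
  y <- 2 * X[, 1] + rnorm(80, sd = 0.01)
  sel <- stepwise_select(X, y, p_threshold = 0.05)
  expect_equal(as.integer(sel), 1L)
  # p-value of a candidate equals the direct partial-F computation
  set.seed(11)
  X6 <- matrix(rnorm(6 * 2), 6, 2)
  y6 <- rnorm(6)
  fit0 <- stats::lm(y6 ~ X6[, 1])
  fit1 <- stats::lm(y6 ~ X6[, 1] + X6[, 2])
  rss0 <- sum(resid(fit0)^2); rss1 <- sum(resid(fit1)^2)
  Fstat <- (rss0 - rss1) / (rss1 / fit1$df.residual)
  p_direct <- stats::pf(Fstat, 1, fit1$df.residual, lower.tail = FALSE)
  a1 <- stats::add1(fit0, ~ . + X6[, 2], test = "F")
  expect_equal(a1[["Pr(>F)"]][2], p_direct, tolerance = 1e-12)
  # thresholds at the extremes
  set.seed(12)
  Xs <- matrix(rnorm(60 * 4), 60, 4)
  ys <- drop(Xs %*% c(1, 1, 1, 1)) + rnorm(60, sd = 0.1)
  expect_length(stepwise_select(Xs, ys, p_threshold = 1e-12), 0)
  expect_equal(as.integer(stepwise_select(Xs, ys, p_threshold = 0.999)), 1:4)
})

test_that("stepwise type-I error stays near the nominal level on pure noise", {
  set.seed(20)
  sizes <- replicate(40, {
    X <- matrix(rnorm(50 * 8), 50, 8)
    length(stepwise_select(X, rnorm(50), p_threshold = 0.005))
  })
  # expected false selections <= M * p_threshold plus margin
  expect_lte(mean(sizes), 8 * 0.005 * 4 + 0.15)
})

test_that("contribution ranking finds the informative group and respects D", {
  sim <- small_sim(seed = 3)
  d <- sim$dataset
  m <- ncol(d$X)
  active <- sim$truth$active_idx
  rest <- setdiff(seq_len(m), active)
  grouping <- structure(list(groups = list(sort(active),
                                           rest[seq_len(length(rest) %/% 2)],
                                           rest[(length(rest) %/% 2 + 1):length(rest)]),
                             ungrouped = integer(0), n_items = m),
                        class = "variable_grouping")
  fit <- ncsc_vs(d, grouping, P = 3, D = 1, cv_folds = 5)
  expect_equal(which.max(fit$contributions), 1L)
  expect_equal(fit$selected_groups, 1L)
  expect_equal(fit$variables, sort(active))
  # contributions match an independent per-group R^2 computation
  yc <- d$y - mean(d$y)
  for (j in 1:3) {
    Xj <- d$X[, grouping$groups[[j]], drop = FALSE]
    pj <- min(3, ncol(Xj))
    oracle_fit <- suppressWarnings(fit_pls(Xj, d$y, pj))
    r2 <- 1 - sum((d$y - oracle_fit$fitted)^2) / sum(yc^2)
    expect_equal(fit$contributions[j], r2, tolerance = 1e-10)
  }
  # D = J keeps every grouped variable
  fit_all <- ncsc_vs(d, grouping, P = 2, D = 3, cv_folds = 5)
  expect_equal(fit_all$variables, sort(unlist(grouping$groups)))
})

test_that("group-lasso selection pipeline returns groups, variables and a model", {
  sim <- small_sim(seed = 9)
  d <- sim$dataset
  aff <- variable_affinity(d, config = nc_config(0.9))
  grouping <- spectral_partition(aff, J = 3, seed = 1)
  fit <- ncsc_gl(d, grouping, lambda = 1, cv_folds = 5)
  expect_true(all(fit$selected_groups %in% seq_along(grouping$groups)))
  expect_true(all(fit$variables %in% unlist(grouping$groups)))
  expect_s3_class(fit$model, "pls_model")
})
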