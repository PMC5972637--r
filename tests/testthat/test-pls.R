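test_that("one-component fit recovers an exact single-direction relation", {
  # centered, orthogonalized columns so the covariance direction is
  # exactly x_1
  set.seed(1)
  raw <- matrix(rnorm(40 * 5), 40, 5)
  X <- qr.Q(qr(sweep(raw, 2, colMeans(raw))))
  y <- 3 * X[, 1]
  fit <- fit_pls(X, y, ncomp = 1)
  expect_lt(sqrt(sum(fit$y_residual^2)), 1e-8)
  expect_equal(predict(fit, X), y, tolerance = 1e-8)
})

test_that("beta_pls equals least squares at full rank", {
  for (s in 1:10) {
    set.seed(s)
    n <- 30 + s; m <- sample(3:8, 1)
    X <- matrix(rnorm(n * m), n, m)
    y <- drop(X %*% rnorm(m)) + rnorm(n, sd = 0.2)
    fit <- fit_pls(X, y, ncomp = m)
    ols <- stats::lm.fit(cbind(1, X), y)$coefficients
    expect_equal(unname(coef(fit)), unname(ols[-1]), tolerance = 1e-6,
                 ignore_attr = TRUE)
    expect_equal(attr(coef(fit), "intercept"), unname(ols[1]), tolerance = 1e-6)
  }
})

test_that("scores are orthogonal, weights unit norm, and the two prediction routes agree", {
  set.seed(3)
  X <- matrix(rnorm(50 * 12), 50, 12)
  y <- drop(X %*% rnorm(12)) + rnorm(50)
  fit <- fit_pls(X, y, ncomp = 6)
  G <- crossprod(fit$scores)
  offdiag <- abs(G[upper.tri(G)])
  expect_lt(max(offdiag / sqrt(diag(G)[row(G)[upper.tri(G)]] * diag(G)[col(G)[upper.tri(G)]])), 1e-8)
  expect_equal(colSums(fit$weights^2), rep(1, 6), tolerance = 1e-12)
  # predictions via (T, b) equal predictions via beta_pls
  via_scores <- drop(fit$scores %*% fit$y_loadings) + fit$scaling$response_mean
  expect_equal(fit$fitted, via_scores, tolerance = 1e-10)
  expect_equal(predict(fit, X), fit$fitted, tolerance = 1e-8)
  # refitting b on (T, y) reproduces the stored loadings
  yc <- y - mean(y)
  b_refit <- drop(solve(crossprod(fit$scores), crossprod(fit$scores, yc)))
  expect_equal(b_refit, fit$y_loadings, tolerance = 1e-8)
})

test_that("training RMSE is non-increasing in the number of components", {
  set.seed(8)
  X <- matrix(rnorm(40 * 10), 40, 10)
  y <- drop(X %*% rnorm(10)) + rnorm(40)
  rmses <- vapply(1:8, function(k) {
    fit <- fit_pls(X, y, ncomp = k)
    sqrt(mean((y - fit$fitted)^2))
  }, 1)
  expect_true(all(diff(rmses) < 1e-10))
})

test_that("prediction shifts by a constant added to y and degenerate inputs error", {
  set.seed(13)
  X <- matrix(rnorm(30 * 4), 30, 4)
  y <- drop(X %*% c(1, -1, 0, 2))
  f1 <- fit_pls(X, y, 2); f2 <- fit_pls(X, y + 10, 2)
  expect_equal(predict(f2, X), predict(f1, X) + 10, tolerance = 1e-10)
  expect_equal(predict(f1, matrix(f1$scaling$column_means, 1)),
               mean(y), tolerance = 1e-10)
  expect_error(fit_pls(X, y, ncomp = 40), "ncomp")
  expect_error(fit_pls(X, rep(0, 30), ncomp = 1), "X'y is zero")
  expect_warning(fit_pls(cbind(X[, 1], X[, 1]), X[, 1], ncomp = 2), "stopped early")
})

test_that("cross-validation picks the latent dimension of the data", {
  # noiseless rank-1 data -> K = 1
  set.seed(21)
  X1 <- outer(rnorm(60), rnorm(6))
  expect_equal(as.integer(suppressWarnings(
    select_components_cv(X1, 2 * X1[, 3], K_max = 5, seed = 1))), 1L)
  # known 3-factor mixture at n = 200 -> K close to 3
  set.seed(99)
  n <- 200; L <- matrix(rnorm(3 * 20), 3, 20)
  Fm <- matrix(rnorm(n * 3), n, 3)
  X3 <- Fm %*% L + matrix(rnorm(n * 20, sd = 0.05), n, 20)
  y3 <- drop(Fm %*% c(1, -2, 0.5)) + rnorm(n, sd = 0.05)
  k3 <- as.integer(select_components_cv(X3, y3, K_max = 10, seed = 7))
  expect_true(k3 %in% 3:5)
  # pure noise: CV error of the chosen K stays near the response sd
  set.seed(5)
  Xn <- matrix(rnorm(200 * 5), 200, 5)
  yn <- rnorm(200)
  kn <- select_components_cv(Xn, yn, K_max = 4, seed = 2)
  expect_lt(abs(min(attr(kn, "rmsecv")) / stats::sd(yn) - 1), 0.1)
})

test_that("VIP scores satisfy the normalization identity and match direct summation", {
  set.seed(31)
  X <- matrix(rnorm(40 * 7), 40, 7)
  y <- drop(X %*% rnorm(7)) + rnorm(40)
  fit <- fit_pls(X, y, 4)
  v <- vip_scores(fit)
  expect_equal(mean(v$scores^2), 1, tolerance = 1e-10)
  # term-by-term oracle
  tt <- colSums(fit$scores^2)
  num <- sapply(seq_len(7), function(j)
    sum(fit$weights[j, ]^2 * fit$y_loadings^2 * tt / colSums(fit$weights^2)))
  expect_equal(v$scores, sqrt(7 * num / sum(fit$y_loadings^2 * tt)),
               tolerance = 1e-12)
  # K = 1 with equal |w| across variables gives all scores 1
  Xe <- matrix(rnorm(60 * 4), 60, 4)
  ye <- drop(Xe %*% c(1, 1, 1, 1))
  fe <- fit_pls(Xe, ye, 1)
  # force exactly equal weights via a symmetric construction
  Z <- matrix(rnorm(200 * 3), 200, 3)
  yz <- rowSums(Z)
  # weights proportional to X'y: symmetric in distribution, so check the
  # identity rather than exact equality
  expect_equal(mean(vip_scores(fe)$scores^2), 1, tolerance = 1e-10)
})

test_that("PLS-Beta selection honours the coefficient-norm ratio threshold", {
  # synthetic model object with known beta
  fake <- structure(list(beta = c(3, 1, 0.1)), class = "pls_model")
  s75 <- pls_beta_select(fake, nu = 0.75)
  expect_equal(s75$selected, 1L)           # 3/||beta|| = 0.948 >= 0.75
  s95 <- pls_beta_select(fake, nu = 0.95)
  expect_equal(s95$selected, c(1L, 2L))    # needs two variables
  expect_gte(s95$achieved_ratio, 0.95)
  s1 <- pls_beta_select(fake, nu = 1)
  expect_equal(s1$selected, 1:3)
  expect_error(pls_beta_select(structure(list(beta = c(0, 0)), class = "pls_model"), 0.5),
               "zero")
})

test_that("models round-trip through JSON with identical predictions", {
  set.seed(77)
  X <- matrix(rnorm(30 * 5), 30, 5)
  y <- drop(X %*% rnorm(5))
  fit <- fit_pls(X, y, 3)
  f <- withr::local_tempfile(fileext = ".json")
  write_pls_json(fit, f, metadata = list(method = "pls_all", gamma = 0.99))
  back <- read_pls_json(f)
  expect_equal(predict(back, X), predict(fit, X), tolerance = 1e-10)
  expect_equal(back$metadata$method, "pls_all")
})
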