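test_that("a variable duplicating the response attains the maximum NCVW weight", {
  set.seed(2)
  n <- 40
  y <- rnorm(n)
  X <- cbind(y, matrix(rnorm(n * 4), n, 4))
  d <- spectra_dataset(X)
  d$y <- y
  w <- ncvw_weights(d, nc_config(0.99))
  expect_equal(unname(which.max(w$weights)), 1L)
  expect_equal(max(w$weights), 1)  # max normalization
  # and across seeded replicates the duplicate never loses to an
  # independent column
  wins <- vapply(1:10, function(s) {
    set.seed(400 + s)
    y <- rnorm(30)
    d <- spectra_dataset(cbind(y, matrix(rnorm(30 * 5), 30, 5)), y = y)
    w <- ncvw_weights(d)
    all(w$weights[1] >= w$weights[-1])
  }, TRUE)
  expect_true(all(wins))
})

test_that("NCVW weights vanish when the response is unrelated to the spectra", {
  zeros <- vapply(1:10, function(s) {
    set.seed(500 + s)
    d <- spectra_dataset(matrix(rnorm(100 * 8), 100, 8), y = rnorm(100))
    max(ncvw_weights(d, normalization = "none")$raw)
  }, 1)
  expect_lte(stats::quantile(zeros, 0.95), 2)
})

test_that("weights equal the response column of the triple-loop affinity oracle", {
  set.seed(6)
  v <- rnorm(25)
  d <- spectra_dataset(cbind(v + rnorm(25, sd = 0.01), -2 * v, rnorm(25)),
                       y = v)
  w <- ncvw_weights(d, nc_config(0.95), normalization = "none")
  oracle <- oracle_affinity(t(cbind(d$X, d$y)), 0.95)
  expect_equal(unname(w$raw), oracle[1:3, 4])
})

test_that("NCVW weights are invariant to translating any variable or the response", {
  set.seed(14)
  d <- spectra_dataset(matrix(rnorm(30 * 5), 30, 5), y = rnorm(30))
  w0 <- ncvw_weights(d, nc_config(0.8))
  d2 <- d; d2$X[, 3] <- d2$X[, 3] + 100
  d3 <- d; d3$y <- d3$y - 42
  expect_equal(ncvw_weights(d2, nc_config(0.8))$raw, w0$raw)
  expect_equal(ncvw_weights(d3, nc_config(0.8))$raw, w0$raw)
  expect_error(ncvw_weights(spectra_dataset(d$X, y = rep(1, 30))), "constant")
})

test_that("CCVW weights are the absolute Pearson correlations", {
  set.seed(8)
  y <- rnorm(20)
  X <- cbind(y, -y, rnorm(20), rep(1, 20))
  d <- spectra_dataset(X, y = y)
  w <- ccvw_weights(d)
  expect_equal(unname(w$raw[1]), 1, tolerance = 1e-12)
  expect_equal(unname(w$raw[2]), -1, tolerance = 1e-12)
  expect_equal(unname(w$raw[3]), stats::cor(X[, 3], y), tolerance = 1e-12)
  expect_equal(unname(w$weights[4]), 0)  # zero-variance column
  expect_equal(unname(w$weights), abs(unname(w$raw)), tolerance = 1e-12)
  # 4-sample hand check
  y4 <- c(1, 2, 3, 4); x4 <- c(2, 1, 5, 3)
  d4 <- spectra_dataset(cbind(x4, y4), y = y4)
  yc <- y4 - mean(y4); xc <- x4 - mean(x4)
  expect_equal(unname(ccvw_weights(d4)$raw[1]),
               sum(yc * xc) / sqrt(sum(yc^2) * sum(xc^2)), tolerance = 1e-12)
})

test_that("apply_weights is an element-wise scaling that preserves labels", {
  set.seed(9)
  d <- spectra_dataset(matrix(rnorm(12), 3, 4), wavelengths = c("a", "b", "c", "d"),
                       y = rnorm(3))
  w <- structure(list(weights = c(1, 0, 0.5, 2), raw = c(1, 0, 0.5, 2),
                      source = "ncvw", normalization = "none", gamma = 0.99),
                 class = "weight_vector")
  z <- apply_weights(d, w)
  expect_equal(z$wavelengths, d$wavelengths)
  expect_equal(z$X[, 2], rep(0, 3), ignore_attr = TRUE)
  expect_equal(z$X, sweep(d$X, 2, c(1, 0, 0.5, 2), `*`))
  # identity weights leave the dataset unchanged
  expect_equal(apply_weights(d, rep(1, 4))$X, d$X)
  # linear in X and commutes with row subsetting
  expect_equal(apply_weights(subset_dataset(d, samples = 1:2), w)$X,
               apply_weights(d, w)$X[1:2, ])
  expect_error(apply_weights(d, c(1, 2)), "mismatch")
  # a zero-weight column gets a zero PLS coefficient after centering-only fit
  set.seed(10)
  dd <- spectra_dataset(matrix(rnorm(40 * 3), 40, 3), y = rnorm(40))
  zz <- apply_weights(dd, c(1, 0, 1))
  fit <- suppressWarnings(fit_pls(zz, ncomp = 2))
  expect_equal(fit$beta[2], 0, tolerance = 1e-12)
})

test_that("the pipeline stores weights and reuses them at prediction time", {
  sim <- small_sim(seed = 17)
  fit <- ncvw_pipeline(sim$dataset, cv_folds = 5, seed = 1)
  expect_s3_class(fit, "weighted_pls")
  expect_equal(fit$weights$gamma, 0.99)  # default honoured when omitted
  manual <- predict(fit$model, apply_weights(sim$validation$X, fit$weights))
  expect_equal(predict(fit, sim$validation), manual, tolerance = 1e-12)
  # ccvw pipeline runs end to end
  fc <- ccvw_pipeline(sim$dataset, cv_folds = 5, seed = 1)
  expect_s3_class(fc, "weighted_pls")
  expect_equal(fc$weights$source, "ccvw")
})

test_that("weights export to CSV with variable labels", {
  sim <- small_sim(seed = 19)
  w <- ncvw_weights(sim$dataset)
  f <- withr::local_tempfile(fileext = ".csv")
  write_weights_csv(w, f)
  back <- utils::read.csv(f)
  expect_equal(nrow(back), ncol(sim$dataset$X))
  expect_equal(back$weight, unname(w$weights))
})
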