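test_that("nc_config validates gamma", {
  expect_error(nc_config(0), "gamma")
  expect_error(nc_config(1.2), "gamma")
  expect_equal(nc_config()$gamma, 0.99)
})

test_that("similarity search finds collinear pairs through the query", {
  # cosine reading: exact collinearity through the translated origin
  pts <- rbind(q = c(0, 0), a = c(1, 1), b = c(2, 2), c = c(1, 0))
  got <- nc_similar_pairs(pts, 1, nc_config(0.99, method = "cosine"))
  expect_equal(unname(got), matrix(c(2L, 3L), 1))
  # Pearson reading, 3-D: two diametric pairs on a plane through the
  # query; off-plane points never appear (the Figure-1 geometry)
  q <- c(1, 1, 1)
  u <- c(1, 0.5, -0.2); v <- c(-0.3, 1, 0.4)
  pts3 <- rbind(q = q,
                x1 = q + u, x4 = q - 2 * u,      # diametric pair along u
                x2 = q + v, x3 = q - 0.5 * v,    # diametric pair along v
                x5 = q + c(5, -4, 9), x6 = q + c(-7, 2, 6))
  got3 <- nc_similar_pairs(pts3, 1, nc_config(0.99))
  expect_equal(unname(got3), rbind(c(2L, 3L), c(4L, 5L)))
  expect_equal(unname(got3), unname(oracle_pairs(pts3, 1, 0.99)))
  # gamma = 1 on generic continuous data: exact collinearity has
  # probability zero
  set.seed(5)
  rnd <- matrix(rnorm(8 * 6), 8, 6)
  expect_equal(nrow(nc_similar_pairs(rnd, 3, nc_config(1))), 0)
  expect_error(nc_similar_pairs(rnd, 9, nc_config()), "query_index")
  expect_error(nc_similar_pairs(rnd[1:2, ], 1, nc_config()), "3 items")
})

test_that("affinity counts match the literal triple-loop oracle", {
  # collinear points: every query flags the pair, count = Q - 2
  line <- cbind(1:4, 2 * (1:4))
  aff <- build_affinity(line, nc_config(0.99, method = "cosine"))
  expect_equal(unname(aff$counts), matrix(2, 4, 4) - diag(2, 4))
  # gamma -> 0+: every defined correlation passes
  set.seed(7)
  pts <- matrix(rnorm(6 * 5), 6, 5)
  aff0 <- build_affinity(pts, nc_config(1e-9))
  expect_equal(unname(aff0$counts), matrix(4, 6, 6) - diag(4, 6))
  # random instances vs oracle at moderate gamma
  for (s in 1:5) {
    set.seed(100 + s)
    items <- matrix(rnorm(7 * 4), 7, 4)
    got <- build_affinity(items, nc_config(0.8))
    expect_equal(unname(got$counts), oracle_affinity(items, 0.8))
  }
})

test_that("affinity is symmetric, zero-diagonal, translation-invariant and monotone in gamma", {
  set.seed(9)
  items <- matrix(rnorm(9 * 5), 9, 5)
  a1 <- build_affinity(items, nc_config(0.7))
  expect_equal(a1$counts, t(a1$counts))
  expect_equal(diag(a1$counts), rep(0, 9))
  expect_true(all(a1$counts <= 9 - 2))
  # common translation of all items leaves counts unchanged
  shifted <- sweep(items, 2, c(3, -1, 2, 0.5, 7), `+`)
  expect_equal(build_affinity(shifted, nc_config(0.7))$counts, a1$counts)
  # monotonicity: larger gamma never increases counts
  a2 <- build_affinity(items, nc_config(0.95))
  expect_true(all(a2$counts <= a1$counts))
})

test_that("variable_affinity treats columns as items and appends the response", {
  set.seed(21)
  v <- rnorm(30); u <- rnorm(30)
  d <- spectra_dataset(cbind(v, 2 * v, u), y = rnorm(30))
  aff <- variable_affinity(d, config = nc_config(0.99))
  expect_equal(unname(aff$counts), oracle_affinity(t(d$X), 0.99))
  # duplicated pair of columns attains the maximum count in the matrix
  expect_equal(aff$counts[1, 2], max(aff$counts))
  affy <- variable_affinity(d, include_response = TRUE)
  expect_equal(dim(affy$counts), c(4, 4))
  expect_equal(rownames(affy$counts)[4], "response")
  expect_error(variable_affinity(spectra_dataset(d$X[1:2, ]), config = nc_config()),
               "3 samples")
})

test_that("fast per-query computation matches the naive loop to 1e-12", {
  # the similarity values themselves (not just the thresholded counts)
  set.seed(33)
  items <- matrix(rnorm(8 * 10), 8, 10)
  L <- 3
  U <- sweep(items, 2, items[L, ])
  C_fast <- ncvw:::nc_similarity(U, "pearson")
  for (k in seq_len(8)) {
    for (l in seq_len(8)) {
      if (k == l || k == L || l == L) next
      expect_equal(C_fast[k, l], stats::cor(U[k, ], U[l, ]), tolerance = 1e-12)
    }
  }
})

test_that("affinity CSV export round-trips labels and counts", {
  set.seed(4)
  d <- spectra_dataset(matrix(rnorm(15 * 4), 15, 4),
                       wavelengths = c("800", "900", "1000", "1100"))
  aff <- variable_affinity(d, config = nc_config(0.6))
  f <- withr::local_tempfile(fileext = ".csv")
  write_affinity_csv(aff, f)
  back <- utils::read.csv(f, check.names = FALSE)
  expect_equal(as.character(back$item), c("800", "900", "1000", "1100"))
  expect_equal(unname(as.matrix(back[, -1])), unname(aff$counts))
})
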