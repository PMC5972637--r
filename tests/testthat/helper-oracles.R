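# Independent oracles used across the suite. These deliberately use naive,
# literal implementations (explicit loops, stats::cor, normal equations) so
# they share no code path with the package's vectorized implementations.

# Literal triple-loop NC affinity: for every query L, translate, compute
# pairwise correlations one at a time with stats::cor, threshold, accumulate.
oracle_affinity <- function(items, gamma, method = c("pearson", "cosine")) {
  method <- match.arg(method)
  q <- nrow(items)
  counts <- matrix(0, q, q)
  for (L in seq_len(q)) {
    U <- sweep(items, 2, items[L, ])
    norms <- sqrt(rowSums(U^2))
    typical <- max(norms)
    for (k in seq_len(q - 1)) {
      for (l in (k + 1):q) {
        if (k == L || l == L) next
        if (norms[k] <= 1e-12 * typical || norms[l] <= 1e-12 * typical) next
        if (method == "pearson") {
          vk <- U[k, ] - mean(U[k, ]); vl <- U[l, ] - mean(U[l, ])
          nk <- sqrt(sum(vk^2)); nl <- sqrt(sum(vl^2))
          if (nk <= 1e-12 * norms[k] || nl <= 1e-12 * norms[l]) next
          cc <- sum(vk * vl) / (nk * nl)
        } else {
          cc <- sum(U[k, ] * U[l, ]) / (norms[k] * norms[l])
        }
        if (!is.na(cc) && abs(cc) >= gamma) {
          counts[k, l] <- counts[k, l] + 1
          counts[l, k] <- counts[l, k] + 1
        }
      }
    }
  }
  counts
}

# Oracle for a single query: the set of flagged pairs, as a sorted
# two-column matrix, k < l.
oracle_pairs <- function(items, query, gamma, method = "pearson") {
  q <- nrow(items)
  counts <- matrix(0, q, q)
  U <- sweep(items, 2, items[query, ])
  norms <- sqrt(rowSums(U^2))
  typical <- max(norms)
  out <- NULL
  for (k in seq_len(q - 1)) {
    for (l in (k + 1):q) {
      if (k == query || l == query) next
      if (norms[k] <= 1e-12 * typical || norms[l] <= 1e-12 * typical) next
      if (method == "pearson") {
        vk <- U[k, ] - mean(U[k, ]); vl <- U[l, ] - mean(U[l, ])
        nk <- sqrt(sum(vk^2)); nl <- sqrt(sum(vl^2))
        if (nk <= 1e-12 * norms[k] || nl <= 1e-12 * norms[l]) next
        cc <- sum(vk * vl) / (nk * nl)
      } else {
        cc <- sum(U[k, ] * U[l, ]) / (norms[k] * norms[l])
      }
      if (abs(cc) >= gamma) out <- rbind(out, c(k, l))
    }
  }
  if (is.null(out)) matrix(integer(0), 0, 2) else out
}

# Exhaustive minimum of the Mcut objective over all bipartitions of up to
# ~12 nodes (2^(n-1) - 1 candidate splits).
oracle_mcut_best <- function(S) {
  n <- nrow(S)
  best <- Inf
  for (code in 1:(2^(n - 1) - 1)) {
    A <- which(bitwAnd(code, 2^(0:(n - 1))) > 0)
    B <- setdiff(seq_len(n), A)
    if (length(B) == 0) next
    wA <- sum(S[A, A]); wB <- sum(S[B, B]); cutw <- sum(S[A, B])
    obj <- if (wA == 0 || wB == 0) Inf else cutw / wA + cutw / wB
    best <- min(best, obj)
  }
  best
}

# Small random regression problem with centered columns.
random_regression <- function(n, m, seed, sd_noise = 0.1) {
  set.seed(seed)
  X <- matrix(rnorm(n * m), n, m)
  X <- sweep(X, 2, colMeans(X))
  beta <- rnorm(m) * rbinom(m, 1, 0.6)
  y <- drop(X %*% beta) + rnorm(n, sd = sd_noise)
  y <- y - mean(y)
  list(X = X, y = y, beta = beta)
}

# Shared small synthetic dataset for module tests (kept small for speed).
small_sim <- function(seed = 42, n = 80, m = 60, ...) {
  simulate_spectra(sim_spec(n_samples = n, n_wavelengths = m,
                            n_validation = 20, seed = seed, ...))
}
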