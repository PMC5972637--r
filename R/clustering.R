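#' Spectral partitioning of an NC affinity graph
#'
#' Partitions the items of an affinity matrix into `J` groups. Items with
#' zero affinity degree carry no grouping information and are reported as
#' `ungrouped` rather than forced into a cluster. The default (`"ng"`)
#' embeds the positive-degree items with the top-J eigenvectors of the
#' symmetrically normalized affinity D^(-1/2) S D^(-1/2), normalizes the
#' embedding rows to unit length, and partitions them by k-means (50
#' restarts, seeded). For J = 2 the classical max-min cut (Mcut) sweep over
#' the second eigenvector is evaluated as well and the bipartition with the
#' lower Mcut objective is returned. `method = "mcut"` performs recursive
#' bisection by that sweep, splitting the largest group until J groups
#' remain.
#'
#' @param affinity an `affinity_matrix` (or plain symmetric nonnegative
#'   matrix with zero diagonal).
#' @param J number of groups, >= 1.
#' @param seed integer seed for k-means restarts.
#' @param method `"ng"` (normalized spectral embedding + k-means, default)
#'   or `"mcut"` (recursive bisection).
#' @return an object of class `variable_grouping`: list with `groups`
#'   (list of J integer index vectors, pairwise disjoint, none empty) and
#'   `ungrouped` (zero-degree indices).
#' @export
spectral_partition <- function(affinity, J, seed = 1L, method = c("ng", "mcut")) {
  method <- match.arg(method)
  S <- if (inherits(affinity, "affinity_matrix")) affinity$counts else
    as_numeric_matrix(affinity, "affinity")
  if (nrow(S) != ncol(S) || any(S < 0) || any(abs(S - t(S)) > 1e-9)) {
    stop("affinity must be a symmetric nonnegative matrix", call. = FALSE)
  }
  check_scalar(J, "J", lower = 1, integer = TRUE)
  deg <- rowSums(S)
  pos <- which(deg > 0)
  ungrouped <- setdiff(seq_len(nrow(S)), pos)
  if (J > length(pos)) {
    stop(sprintf("J = %d exceeds the %d items with positive affinity degree",
                 J, length(pos)), call. = FALSE)
  }
  if (J == 1L) {
    return(new_grouping(list(pos), ungrouped, nrow(S)))
  }
  S0 <- S[pos, pos, drop = FALSE]
  groups_local <- if (method == "ng") {
    ng_partition(S0, J, seed)
  } else {
    mcut_bisection(S0, J)
  }
  groups <- lapply(groups_local, function(g) pos[g])
  new_grouping(groups, ungrouped, nrow(S))
}

new_grouping <- function(groups, ungrouped, n_items) {
  groups <- lapply(groups, function(g) sort(as.integer(g)))
  keep <- lengths(groups) > 0L
  structure(list(groups = groups[keep], ungrouped = sort(as.integer(ungrouped)),
                 n_items = n_items),
            class = "variable_grouping")
}

#' @export
print.variable_grouping <- function(x, ...) {
  cat(sprintf("variable_grouping: %d groups (sizes %s), %d ungrouped of %d items\n",
              length(x$groups), paste(lengths(x$groups), collapse = ", "),
              length(x$ungrouped), x$n_items))
  invisible(x)
}

# Normalized spectral embedding (top-J eigenvectors of D^-1/2 S D^-1/2,
# rows unit-normalized) followed by seeded k-means.
ng_partition <- function(S0, J, seed) {
  d <- rowSums(S0)
  Ls <- S0 / sqrt(outer(d, d))
  ev <- eigen(Ls, symmetric = TRUE)
  U <- ev$vectors[, seq_len(J), drop = FALSE]
  rn <- sqrt(rowSums(U^2))
  rn[rn == 0] <- 1
  U <- U / rn
  km <- with_local_seed(seed, stats::kmeans(U, centers = J, nstart = 50L,
                                            iter.max = 100L))
  groups <- split(seq_len(nrow(S0)), km$cluster)
  if (J == 2L) {
    # refine the k-means bipartition, the classical eigenvector sweep cuts,
    # and a few seeded random restarts by greedy node exchanges, keeping
    # the candidate with the lowest Mcut objective
    n0 <- nrow(S0)
    candidates <- list(unname(groups))
    for (col in 2:min(3L, ncol(ev$vectors))) {
      sw <- mcut_sweep(S0, ev$vectors[, col])
      if (!is.null(sw)) candidates <- c(candidates, list(sw))
    }
    candidates <- c(candidates, with_local_seed(seed + 1L, lapply(1:10, function(i) {
      side <- sample(c(TRUE, FALSE), n0, replace = TRUE)
      if (all(side) || !any(side)) side[1L] <- !side[1L]
      list(which(side), which(!side))
    })))
    candidates <- lapply(candidates, function(g) refine_bipartition(S0, g))
    objs <- vapply(candidates, function(g)
      mcut_objective(S0, membership(g, n0)), 1)
    groups <- candidates[[which.min(objs)]]
  }
  unname(groups)
}

# Greedy refinement of a bipartition under the Mcut objective: single-node
# moves, then pairwise swaps across the cut, iterated to a local optimum.
# Keeps both sides non-empty.
refine_bipartition <- function(S0, groups) {
  n <- nrow(S0)
  lab <- membership(groups, n)
  obj <- mcut_objective(S0, lab)
  repeat {
    improved <- FALSE
    for (i in seq_len(n)) {
      if (sum(lab == lab[i]) <= 1L) next
      trial <- lab
      trial[i] <- 3L - lab[i]
      o <- mcut_objective(S0, trial)
      if (o < obj - 1e-12) {
        lab <- trial
        obj <- o
        improved <- TRUE
      }
    }
    if (improved) next
    for (i in which(lab == 1L)) {
      for (j in which(lab == 2L)) {
        trial <- lab
        trial[i] <- 2L; trial[j] <- 1L
        o <- mcut_objective(S0, trial)
        if (o < obj - 1e-12) {
          lab <- trial
          obj <- o
          improved <- TRUE
        }
      }
    }
    if (!improved) break
  }
  list(which(lab == 1L), which(lab == 2L))
}

membership <- function(groups, n) {
  lab <- integer(n)
  for (j in seq_along(groups)) lab[groups[[j]]] <- j
  lab
}

# Ding-style threshold sweep on an eigenvector ordering: evaluate the Mcut
# objective of every prefix bipartition and keep the best.
mcut_sweep <- function(S0, v) {
  n <- nrow(S0)
  ord <- order(v)
  best <- NULL; best_obj <- Inf
  for (cut in seq_len(n - 1L)) {
    A <- ord[seq_len(cut)]
    B <- ord[(cut + 1L):n]
    obj <- mcut_objective(S0, membership(list(A, B), n))
    if (obj < best_obj) {
      best_obj <- obj
      best <- list(A, B)
    }
  }
  best
}

mcut_bisection <- function(S0, J) {
  groups <- list(seq_len(nrow(S0)))
  while (length(groups) < J) {
    sizes <- lengths(groups)
    splittable <- which(sizes >= 2L)
    if (length(splittable) == 0L) {
      stop("cannot split further: groups are singletons", call. = FALSE)
    }
    target <- splittable[which.max(sizes[splittable])]
    idx <- groups[[target]]
    Ssub <- S0[idx, idx, drop = FALSE]
    d <- rowSums(Ssub)
    if (all(d == 0)) {  # disconnected singleton-ish remainder: split arbitrarily
      parts <- list(idx[1L], idx[-1L])
    } else {
      d[d == 0] <- min(d[d > 0]) * 1e-6
      Ls <- Ssub / sqrt(outer(d, d))
      v <- eigen(Ls, symmetric = TRUE)$vectors[, min(2L, ncol(Ls))]
      sub <- refine_bipartition(Ssub, mcut_sweep(Ssub, v))
      parts <- list(idx[sub[[1L]]], idx[sub[[2L]]])
    }
    groups <- c(groups[-target], parts)
  }
  groups
}

#' Max-min cut (Mcut) objective of a partition
#'
#' `sum_j cut(V_j, complement) / within(V_j)` where `within` is the total
#' affinity inside a group (both triangles) and `cut` the affinity leaving
#' it. A group with zero internal affinity yields `Inf`.
#'
#' @param affinity affinity matrix (object or plain matrix).
#' @param labels integer group label per item (0 = ignore the item).
#' @return the objective value.
#' @export
mcut_objective <- function(affinity, labels) {
  S <- if (inherits(affinity, "affinity_matrix")) affinity$counts else as.matrix(affinity)
  labels <- as.integer(labels)
  stopifnot(length(labels) == nrow(S))
  obj <- 0
  for (j in sort(unique(labels[labels > 0L]))) {
    inA <- labels == j
    within <- sum(S[inA, inA])
    cutw <- sum(S[inA, !inA])
    obj <- obj + if (within == 0) Inf else cutw / within
  }
  obj
}

#' Extract per-group column matrices
#'
#' @param dataset a [spectra_dataset()].
#' @param grouping a [spectral_partition()] result.
#' @return list of matrices `X_j`, one per group, columns in index order.
#' @export
group_matrices <- function(dataset, grouping) {
  stopifnot(inherits(dataset, "spectra_dataset"),
            inherits(grouping, "variable_grouping"))
  m <- ncol(dataset$X)
  all_idx <- unlist(grouping$groups)
  if (length(all_idx) && (max(all_idx) > m || min(all_idx) < 1L)) {
    stop("grouping indices out of range for this dataset", call. = FALSE)
  }
  lapply(grouping$groups, function(g) dataset$X[, g, drop = FALSE])
}

#' Export a variable grouping as JSON
#'
#' Maps group ids to variable labels (plus the ungrouped labels).
#'
#' @param grouping a `variable_grouping`.
#' @param labels variable labels (length = number of items).
#' @param file output path.
#' @return invisibly, `grouping`.
#' @export
write_grouping_json <- function(grouping, labels, file) {
  stopifnot(inherits(grouping, "variable_grouping"))
  out <- list(
    groups = stats::setNames(
      lapply(grouping$groups, function(g) as.character(labels[g])),
      paste0("group_", seq_along(grouping$groups))),
    ungrouped = as.character(labels[grouping$ungrouped]))
  jsonlite::write_json(out, file, auto_unbox = FALSE, pretty = TRUE)
  invisible(grouping)
}
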