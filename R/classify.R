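# Subvolumes as a voxels x n matrix, optionally restricted to a mask
stack_subvolumes <- function(subvolumes, mask = NULL) {
  d <- dim(subvolumes[[1]]$data)
  for (sv in subvolumes)
    if (!identical(dim(sv$data), d))
      ng_error("subvolumes must share one shape", "ng_shape_mismatch")
  sel <- if (is.null(mask)) rep(TRUE, prod(d)) else as.logical(mask)
  if (!is.null(mask) && !identical(dim(mask), d))
    ng_error("mask shape must match subvolume shape", "ng_shape_mismatch")
  vapply(subvolumes, function(sv) as.numeric(sv$data[sel]),
         numeric(sum(sel)))
}

# Column-standardize (mean 0, unit norm); constant columns become zero
unit_columns <- function(M) {
  M <- sweep(M, 2, colMeans(M))
  nrm <- sqrt(colSums(M^2))
  nrm[nrm == 0] <- 1
  sweep(M, 2, nrm, "/")
}

#' Simulated-annealing multireference classification
#'
#' Classifies pre-aligned subvolumes into `n_classes` by iterated masked
#' normalized cross-correlation against class averages. Initial averages
#' are built by assigning every subvolume to `oversampling` random classes.
#' During the first `sa_iters` iterations a stochastic hill-climbing rule
#' with simulated annealing is applied: each subvolume takes its
#' best-correlating class unless a randomly proposed alternative is
#' accepted with probability exp((score_alt - score_best) * score_scale /
#' T), with the temperature T stepping linearly from 10 down to 0 over the
#' annealing iterations. Afterwards assignment is strict best-score, and
#' the run terminates at class convergence (< 1% of subvolumes changing
#' class in an iteration) or after `max_iters` further iterations. Empty
#' classes are permitted (their average is frozen until repopulated).
#'
#' Randomness is keyed per subvolume identity (`subvolume_ids`), so
#' permuting the input order together with its ids permutes the assignments
#' identically.
#'
#' @param subvolumes List of equally shaped [voxel_volume()]s.
#' @param n_classes Number of classes (default 10).
#' @param oversampling Random initial classes per subvolume (default 2).
#' @param sa_iters Annealing iterations (default 10; temperature 10 -> 0).
#' @param max_iters Post-annealing iteration cap (default 30).
#' @param mask Optional binary focus mask (same shape as the subvolumes).
#' @param seed Integer seed.
#' @param score_scale Correlation-to-temperature scale (default 100): the
#'   acceptance rule sees score differences multiplied by this factor, so
#'   the nominal 10 -> 0 temperature ramp spans correlation differences of
#'   order 0.1.
#' @param subvolume_ids Integer identities used to key the randomness
#'   (default `seq_along(subvolumes)`).
#' @return A `classification_state`: `assignments` (1-based class labels),
#'   `class_averages` (list of [voxel_volume()]), `iteration`,
#'   `fraction_changed`, `converged`, and `history` (per-iteration
#'   temperature and fraction changed).
#' @export
sa_multireference_classify <- function(subvolumes, n_classes = 10L,
                                       oversampling = 2L, sa_iters = 10L,
                                       max_iters = 30L, mask = NULL,
                                       seed = 1L, score_scale = 100,
                                       subvolume_ids = seq_along(subvolumes)) {
  n <- length(subvolumes)
  ng_stopifnot(n_classes >= 2, "n_classes must be >= 2")
  if (n < n_classes)
    ng_error("fewer subvolumes than classes", "ng_invalid_argument")
  d <- dim(subvolumes[[1]]$data)
  X <- stack_subvolumes(subvolumes, mask)
  Xu <- unit_columns(X)
  temps <- if (sa_iters > 0) seq(10, 0, length.out = sa_iters) else numeric()
  # initial averages from oversampled random memberships
  member <- matrix(0, n, n_classes)
  for (i in seq_len(n)) {
    u <- vapply(seq_len(n_classes), function(k)
      hash_uniform(seed, 0L, subvolume_ids[i], k), 0)
    pick <- order(u)[seq_len(min(oversampling, n_classes))]
    member[i, pick] <- 1
  }
  averages <- X %*% member
  occ <- colSums(member)
  averages <- sweep(averages, 2, pmax(occ, 1), "/")
  assignments <- rep(NA_integer_, n)
  history <- list()
  total_iters <- sa_iters + max_iters
  converged <- FALSE
  for (it in seq_len(total_iters)) {
    S <- crossprod(Xu, unit_columns(averages))   # n x n_classes correlations
    best <- max.col(S, ties.method = "first")
    new_assign <- best
    if (it <= sa_iters) {
      temp <- temps[it]
      for (i in seq_len(n)) {
        alt <- 1L + floor(hash_uniform(seed, it, subvolume_ids[i], 1L) *
                            n_classes)
        alt <- min(alt, n_classes)
        if (alt != best[i]) {
          p_acc <- if (temp > 0)
            exp((S[i, alt] - S[i, best[i]]) * score_scale / temp) else 0
          if (hash_uniform(seed, it, subvolume_ids[i], 2L) < p_acc)
            new_assign[i] <- alt
        }
      }
    } else {
      temp <- 0
    }
    frac <- if (all(is.na(assignments))) 1
            else mean(new_assign != assignments)
    assignments <- new_assign
    # recompute averages; empty classes keep their previous average
    for (k in seq_len(n_classes)) {
      members <- which(assignments == k)
      if (length(members))
        averages[, k] <- rowMeans(X[, members, drop = FALSE])
    }
    history[[it]] <- list(iteration = it, temperature = temp,
                          fraction_changed = frac,
                          phase = if (it <= sa_iters) "annealing" else "hill")
    if (it > sa_iters && frac < 0.01) { converged <- TRUE; break }
  }
  avg_vols <- lapply(seq_len(n_classes), function(k) {
    full <- array(0, dim = d)
    sel <- if (is.null(mask)) rep(TRUE, prod(d)) else as.logical(mask)
    full[sel] <- averages[, k]
    voxel_volume(full, voxel_size = subvolumes[[1]]$voxel_size)
  })
  structure(list(assignments = assignments, class_averages = avg_vols,
                 iteration = length(history),
                 fraction_changed = history[[length(history)]]$fraction_changed,
                 converged = converged, temperature_schedule = temps,
                 seed = seed, n_classes = n_classes, history = history),
            class = "classification_state")
}

# Hungarian algorithm (O(n^3), potentials formulation) for square cost
# matrices; returns for each row the assigned column, minimizing total
# cost. Indices carry a +1 offset for the sentinel row/column 0.
solve_assignment <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  u <- numeric(n + 1)
  v <- numeric(n + 1)
  p <- integer(n + 1)          # p[j+1]: row assigned to column j (0 = none)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(Inf, n + 1)
    used <- logical(n + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]; delta <- Inf; j1 <- 0L
      for (j in seq_len(n)) {
        if (used[j + 1]) next
        cur <- cost[i0, j] - u[i0 + 1] - v[j + 1]
        if (cur < minv[j + 1]) { minv[j + 1] <- cur; way[j + 1] <- j0 }
        if (minv[j + 1] < delta) { delta <- minv[j + 1]; j1 <- j }
      }
      for (j in 0:n) {
        if (used[j + 1]) {
          u[p[j + 1] + 1] <- u[p[j + 1] + 1] + delta
          v[j + 1] <- v[j + 1] - delta
        } else {
          minv[j + 1] <- minv[j + 1] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assign_row <- integer(n)
  for (j in seq_len(n)) if (p[j + 1] > 0) assign_row[p[j + 1]] <- j
  assign_row
}

#' Quorum consensus over classification replicates
#'
#' Reconciles class labels across independently seeded classification
#' replicates, then assigns each subvolume its modal reconciled label if
#' the mode occurs at least `quorum` times, else leaves it unassigned.
#'
#' Two reconciliation routes are provided. With `n_major = NULL`, class
#' averages are matched one-to-one against replicate 1 (Hungarian
#' assignment on pairwise average correlations) — appropriate when the
#' number of classes matches the true heterogeneity. When classification
#' deliberately oversplits (e.g. 10 classes for ~3 structural states),
#' give `n_major`: all replicates' class averages are pooled and
#' hierarchically clustered into `n_major` major classes (see
#' [cluster_class_averages()]), and the quorum vote runs on the major
#' labels.
#'
#' @param replicates List of `classification_state`s over the identical
#'   subvolume set (>= 2).
#' @param quorum Minimum agreement count (default 5, mirroring a 5-of-6
#'   rule).
#' @param n_major Optional number of major classes for cluster-based
#'   reconciliation.
#' @return A `consensus_assignment`: `labels` (NA = unassigned),
#'   `agreement_count`, `n_replicates`, and the reconciled label matrix.
#' @export
replicate_consensus <- function(replicates, quorum = 5L, n_major = NULL) {
  if (length(replicates) < 2)
    ng_error("need at least 2 replicates", "ng_invalid_argument")
  n <- length(replicates[[1]]$assignments)
  k <- replicates[[1]]$n_classes
  for (r in replicates) {
    if (length(r$assignments) != n)
      ng_error("replicates cover different subvolume sets",
               "ng_shape_mismatch")
    if (r$n_classes != k)
      ng_error("replicates disagree on the number of classes",
               "ng_shape_mismatch")
  }
  relabeled <- matrix(NA_integer_, n, length(replicates))
  if (is.null(n_major)) {
    ref <- unit_columns(vapply(replicates[[1]]$class_averages,
                               function(v) as.numeric(v$data),
                               numeric(length(replicates[[1]]$class_averages[[1]]$data))))
    relabeled[, 1] <- replicates[[1]]$assignments
    for (r in seq_along(replicates)[-1]) {
      cur <- unit_columns(vapply(replicates[[r]]$class_averages,
                                 function(v) as.numeric(v$data),
                                 numeric(nrow(ref))))
      sim <- crossprod(cur, ref)          # k x k: cur class vs ref class
      mapping <- solve_assignment(-sim)   # maximize correlation
      relabeled[, r] <- mapping[replicates[[r]]$assignments]
    }
    n_out <- k
  } else {
    all_avgs <- unlist(lapply(replicates, `[[`, "class_averages"),
                       recursive = FALSE)
    major <- cluster_class_averages(all_avgs, n_major)
    for (r in seq_along(replicates)) {
      mapping <- major[(r - 1) * k + seq_len(k)]
      relabeled[, r] <- mapping[replicates[[r]]$assignments]
    }
    n_out <- n_major
  }
  labels <- rep(NA_integer_, n)
  agreement <- integer(n)
  for (i in seq_len(n)) {
    tab <- tabulate(relabeled[i, ], nbins = n_out)
    agreement[i] <- max(tab)
    if (agreement[i] >= quorum) labels[i] <- which.max(tab)
  }
  structure(list(labels = labels, agreement_count = agreement,
                 n_replicates = length(replicates), quorum = quorum,
                 relabeled = relabeled),
            class = "consensus_assignment")
}

#' Hierarchical clustering of class averages
#'
#' Average-linkage hierarchical clustering of class averages on the
#' distance 1 - masked normalized cross-correlation, cut into `n_major`
#' clusters. Used to group the class averages of several replicates into
#' the major structural classes.
#'
#' @param averages List of equally shaped [voxel_volume()]s.
#' @param n_major Number of clusters to cut (<= number of averages).
#' @param mask Optional binary mask restricting the correlation.
#' @return Integer cluster labels, one per input average.
#' @export
cluster_class_averages <- function(averages, n_major, mask = NULL) {
  if (n_major > length(averages))
    ng_error("n_major exceeds the number of averages", "ng_invalid_argument")
  M <- unit_columns(stack_subvolumes(averages, mask))
  corr <- crossprod(M)
  dis <- stats::as.dist(1 - corr)
  hc <- stats::hclust(dis, method = "average")
  stats::cutree(hc, k = n_major)
}

#' Build a variability focus mask from replicate class averages
#'
#' Marks the voxels in the top decile of across-average variance — the most
#' variable region of the structure — for focused reclassification.
#'
#' @param averages List of equally shaped [voxel_volume()]s.
#' @param top_fraction Fraction of most-variable voxels to keep (default
#'   0.1).
#' @return A logical array of the subvolume shape.
#' @export
variance_focus_mask <- function(averages, top_fraction = 0.1) {
  M <- stack_subvolumes(averages)
  v <- apply(M, 1, stats::var)
  thr <- stats::quantile(v, 1 - top_fraction)
  array(v >= thr, dim = dim(averages[[1]]$data))
}
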