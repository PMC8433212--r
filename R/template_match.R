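#' Construct a template volume
#'
#' A matching reference: a density grid plus a binary mask of identical
#' shape selecting the voxels that take part in correlation scoring.
#'
#' @param density A [voxel_volume()].
#' @param mask Logical/0-1 array of the same shape (default: all voxels).
#' @return An object of class `template_volume`.
#' @export
template_volume <- function(density, mask = NULL) {
  assert_volume(density)
  if (is.null(mask)) mask <- array(TRUE, dim = dim(density$data))
  if (!identical(dim(mask), dim(density$data)))
    ng_error("mask shape must match density shape", "ng_invalid_argument")
  mask <- array(as.logical(mask), dim = dim(mask))
  if (!any(mask))
    ng_error("template mask is empty", "ng_empty_template")
  structure(list(density = density, mask = mask), class = "template_volume")
}

#' Build a featureless (rotationally averaged) reference
#'
#' Averages picked particle subvolumes after rotating each by an
#' independent uniformly random orientation, yielding an approximately
#' spherically symmetric, unstructured reference that carries the size and
#' contrast of the particles but none of their internal features — the
#' starting point of reference-bias-free template matching.
#'
#' @param subvolumes List of equally shaped [voxel_volume()]s (>= 2).
#' @param seed Integer seed; the reference is deterministic given it.
#' @return A [template_volume()] with an all-ones mask.
#' @export
build_featureless_reference <- function(subvolumes, seed = 1L) {
  if (length(subvolumes) < 2)
    ng_error("need at least 2 subvolumes", "ng_invalid_argument")
  d <- dim(subvolumes[[1]]$data)
  for (sv in subvolumes)
    if (!identical(dim(sv$data), d))
      ng_error("subvolumes must share one shape", "ng_shape_mismatch")
  with_rng_seed(seed, {
    acc <- array(0, dim = d)
    for (sv in subvolumes) {
      R <- random_rotation_matrix()
      acc <- acc + rotate_array(sv$data, R, fill = mean(sv$data))
    }
    template_volume(voxel_volume(acc / length(subvolumes),
                                 voxel_size = subvolumes[[1]]$voxel_size))
  })
}

#' Truncate a reference with a spherical erasure mask
#'
#' Computationally removes density inside a sphere: erased voxels are set to
#' the template's background mean and excluded from the scoring mask; every
#' other voxel is bit-identical to the input. Two such truncations of one
#' reference drive the dual-reference consensus that suppresses template
#' bias.
#'
#' @param template A [template_volume()].
#' @param sphere_center Length-3, 0-based voxel coordinates of the erasure
#'   sphere center.
#' @param sphere_radius Erasure radius in voxels.
#' @return The truncated [template_volume()].
#' @export
truncate_reference <- function(template, sphere_center, sphere_radius) {
  stopifnot(inherits(template, "template_volume"))
  d <- dim(template$density$data)
  g <- grid_coords(d)
  inside <- colSums((g - sphere_center)^2) <= sphere_radius^2
  region <- array(inside, dim = d)
  if (!any(region)) return(template)
  new_mask <- template$mask & !region
  if (!any(new_mask))
    ng_error("erasure sphere covers the entire template", "ng_empty_template")
  bg <- mean(template$density$data[!region])
  dens <- template$density$data
  dens[region] <- bg
  template$density$data <- dens
  template$mask <- new_mask
  template
}

# Zero-padded FFT cross-correlation: returns sum_x f(x+u) k(x) for
# non-negative offsets u (exact on the valid region u <= dim(f)-dim(k)).
fft_xcorr <- function(f_hat, kernel, vol_dim) {
  kp <- array(0, dim = vol_dim)
  kd <- dim(kernel)
  kp[1:kd[1], 1:kd[2], 1:kd[3]] <- kernel
  Re(stats::fft(f_hat * Conj(stats::fft(kp)), inverse = TRUE)) /
    prod(vol_dim)
}

# Logical array of strict-neighborhood local maxima (26-neighborhood),
# ties kept
local_maxima_26 <- function(arr) {
  d <- dim(arr)
  pad <- array(-Inf, dim = d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- arr
  out <- array(TRUE, dim = d)
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    shifted <- pad[(2 + dx):(d[1] + 1 + dx),
                   (2 + dy):(d[2] + 1 + dy),
                   (2 + dz):(d[3] + 1 + dz)]
    out <- out & (arr >= shifted)
  }
  out
}

#' Masked, locally normalized template matching
#'
#' Computes the masked normalized cross-correlation of a template against a
#' volume at every valid translation (FFT accelerated): under the template
#' mask, both template and local volume patch are mean-subtracted and
#' variance-normalized, so scores lie in \[-1, 1\] and are invariant to
#' affine intensity changes of the volume. Peaks are extracted greedily by
#' descending score with non-maximum suppression.
#'
#' @param vol A [voxel_volume()] to search.
#' @param template A [template_volume()] strictly smaller than `vol` in
#'   every axis.
#' @param top_n Maximum number of peaks to return (600 for the initial
#'   featureless-reference search, 400 per truncated reference).
#' @param nms_radius Suppression radius in voxels (default: half the
#'   smallest template edge).
#' @param tomogram_id Identifier stamped on the returned hits.
#' @return A [particle_table()] of peak positions (template centers,
#'   0-based voxels) with scores sorted descending; attribute `score_map`
#'   is not retained.
#' @export
match_template <- function(vol, template, top_n = 600L, nms_radius = NULL,
                           tomogram_id = "tomo_1") {
  assert_volume(vol)
  stopifnot(inherits(template, "template_volume"))
  vd <- dim(vol$data)
  kd <- dim(template$density$data)
  if (any(kd >= vd))
    ng_error("template must be smaller than the volume in every axis",
             "ng_template_too_large")
  if (is.null(nms_radius)) nms_radius <- floor(min(kd) / 2)
  m <- template$mask * 1
  tdat <- template$density$data
  n_m <- sum(m)
  tbar <- sum(tdat * m) / n_m
  tz <- (tdat - tbar) * m
  tnorm <- sqrt(sum(m * (tdat - tbar)^2))
  if (tnorm == 0)
    ng_error("template is constant under its mask", "ng_degenerate_input")
  f_hat <- stats::fft(vol$data)
  f2_hat <- stats::fft(vol$data^2)
  num <- fft_xcorr(f_hat, tz, vd)
  s1 <- fft_xcorr(f_hat, m, vd)
  s2 <- fft_xcorr(f2_hat, m, vd)
  valid <- vd - kd + 1L
  idx <- list(1:valid[1], 1:valid[2], 1:valid[3])
  num <- num[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  s1 <- s1[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  s2 <- s2[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  den <- tnorm * sqrt(pmax(s2 - s1^2 / n_m, 0))
  score <- array(0, dim = valid)
  ok <- den > 1e-9 * tnorm
  score[ok] <- pmin(1, pmax(-1, num[ok] / den[ok]))
  lm <- local_maxima_26(score)
  cand <- which(lm)
  if (!length(cand))
    return(particle_table(character(), numeric(), numeric(), numeric()))
  cand <- cand[order(score[cand], decreasing = TRUE)]
  cand <- utils::head(cand, max(50L * top_n, 5000L))
  i0 <- cand - 1
  px <- i0 %% valid[1]
  py <- (i0 %/% valid[1]) %% valid[2]
  pz <- i0 %/% (valid[1] * valid[2])
  keep <- .nms_select(cbind(px, py, pz), nms_radius, as.integer(top_n))
  ctr <- (kd - 1) / 2
  particle_table(rep(tomogram_id, length(keep)),
                 px[keep] + ctr[1], py[keep] + ctr[2], pz[keep] + ctr[3],
                 score = score[cand[keep]],
                 provenance = "match_template")
}

#' Dual-reference proximity consensus
#'
#' Retains a particle when the two hit lists (from two differently
#' truncated references) contain points within `max_distance` voxels of one
#' another (Euclidean, at the matching scale). Matching is greedy by
#' ascending pair distance and mutual: each hit is used at most once. The
#' retained particle sits at the pair midpoint with the mean of the two
#' scores; the result is identical whichever list comes first.
#'
#' @param hits_a,hits_b [particle_table()]s from [match_template()] with a
#'   common tomogram_id.
#' @param max_distance Consensus distance in voxels (default 4).
#' @return A [particle_table()] of consensus particles.
#' @export
consensus_filter <- function(hits_a, hits_b, max_distance = 4) {
  ta <- unique(hits_a$tomogram_id); tb <- unique(hits_b$tomogram_id)
  if (length(ta) > 1 || length(tb) > 1 ||
      (length(ta) == 1 && length(tb) == 1 && ta != tb))
    ng_error("hit lists must come from one common tomogram",
             "ng_invalid_argument")
  na <- nrow(hits_a); nb <- nrow(hits_b)
  empty <- particle_table(character(), numeric(), numeric(), numeric())
  if (na == 0 || nb == 0) return(empty)
  pa <- as.matrix(hits_a[, c("x", "y", "z")])
  pb <- as.matrix(hits_b[, c("x", "y", "z")])
  d2 <- outer(rowSums(pa^2), rep(1, nb)) +
        outer(rep(1, na), rowSums(pb^2)) - 2 * pa %*% t(pb)
  d2 <- pmax(d2, 0)
  cand <- which(d2 <= max_distance^2, arr.ind = TRUE)
  if (!nrow(cand)) return(empty)
  dist <- sqrt(d2[cand])
  ord <- order(dist, cand[, 1], cand[, 2])
  used_a <- logical(na); used_b <- logical(nb)
  keep_a <- integer(); keep_b <- integer()
  for (k in ord) {
    i <- cand[k, 1]; j <- cand[k, 2]
    if (used_a[i] || used_b[j]) next
    used_a[i] <- TRUE; used_b[j] <- TRUE
    keep_a <- c(keep_a, i); keep_b <- c(keep_b, j)
  }
  mid <- (pa[keep_a, , drop = FALSE] + pb[keep_b, , drop = FALSE]) / 2
  particle_table(rep(if (length(ta)) ta else "tomo", length(keep_a)),
                 mid[, 1], mid[, 2], mid[, 3],
                 score = (hits_a$score[keep_a] + hits_b$score[keep_b]) / 2,
                 provenance = "consensus_filter")
}
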