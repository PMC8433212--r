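# Physical constants of the mass conversion
.protein_density_g_cm3 <- 1.3
.dalton_g <- 1.66054e-24

#' Convert a voxel count to a protein mass
#'
#' Mass in Dalton of a segmented object occupying `voxel_count` voxels,
#' assuming the standard protein density of 1.3 g/cm^3:
#' mass = voxel_count x (voxel_size in cm)^3 x 1.3 / 1.66054e-24.
#' At the 13.68 A working voxel size one voxel corresponds to ~2004 Da.
#'
#' @param voxel_count Non-negative integer voxel count (vectorized).
#' @param voxel_size Voxel edge in Angstrom.
#' @return Mass in Dalton.
#' @export
voxels_to_mass <- function(voxel_count, voxel_size) {
  ng_stopifnot(all(voxel_count >= 0), "voxel_count must be >= 0")
  ng_stopifnot(voxel_size > 0, "voxel_size must be positive")
  voxel_count * (voxel_size * 1e-8)^3 * .protein_density_g_cm3 / .dalton_g
}

# Label the above-threshold voxels; returns a data.frame of components with
# 0-based centroids and voxel counts.
segment_components <- function(vol, threshold, min_voxels = 2L) {
  mask <- vol$data >= threshold
  labels <- .label_components_26(as.logical(mask), dim(vol$data))
  ncomp <- attr(labels, "n_components")
  empty <- data.frame(label = integer(), cx = numeric(), cy = numeric(),
                      cz = numeric(), voxel_count = integer())
  if (ncomp == 0) {
    attr(empty, "discarded_voxels") <- 0L
    return(empty)
  }
  fg <- which(labels > 0L)
  lab <- labels[fg]
  d <- dim(vol$data)
  # 0-based coordinates of foreground voxels from linear indices
  i0 <- fg - 1
  x <- i0 %% d[1]
  y <- (i0 %/% d[1]) %% d[2]
  z <- i0 %/% (d[1] * d[2])
  cnt <- tabulate(lab, nbins = ncomp)
  cx <- rowsum(x, lab)[, 1] / cnt
  cy <- rowsum(y, lab)[, 1] / cnt
  cz <- rowsum(z, lab)[, 1] / cnt
  keep <- cnt >= min_voxels
  out <- data.frame(label = which(keep), cx = cx[keep], cy = cy[keep],
                    cz = cz[keep], voxel_count = cnt[keep])
  attr(out, "discarded_voxels") <- sum(cnt[!keep])
  out
}

#' Calibrate the binarization threshold against reference particles
#'
#' Starting from a high threshold on the standardized density scale and
#' decreasing in fixed steps, returns the first threshold at which the mean
#' mass of the connected components nearest the reference positions (one
#' per reference, searched within `box_radius`) reaches `target_mass`. This
#' anchors the absolute binarization level to particles of known identity
#' (mean pre-ribosome mass ~4.5 MDa) before segmenting the whole volume.
#'
#' @param vol A standardized, filtered [voxel_volume()].
#' @param reference_positions A [particle_table()] with >= 5 rows (0-based
#'   voxel coordinates).
#' @param target_mass Target mean mass in Da (default 4.5 MDa).
#' @param box_radius Search radius around each reference, voxels.
#' @param start,step,minimum Threshold descent schedule (standardized
#'   units).
#' @param min_voxels Minimum component size, as in [segment_objects()].
#' @return The calibrated threshold, with attributes `reference_masses`
#'   (Da, one per reference; NA where no component was found) and
#'   `mean_mass`.
#' @export
calibrate_threshold <- function(vol, reference_positions,
                                target_mass = 4.5e6, box_radius = 12,
                                start = 5, step = 0.05, minimum = 0,
                                min_voxels = 2L) {
  assert_volume(vol)
  if (nrow(reference_positions) < 5)
    ng_error("threshold calibration needs at least 5 reference positions",
             "ng_too_few_points")
  ng_stopifnot(target_mass > 0, "target_mass must be positive")
  refs <- as.matrix(reference_positions[, c("x", "y", "z")])
  thresholds <- seq(start, minimum, by = -abs(step))
  for (thr in thresholds) {
    comp <- segment_components(vol, thr, min_voxels = min_voxels)
    if (!nrow(comp)) next
    masses <- rep(NA_real_, nrow(refs))
    cc <- as.matrix(comp[, c("cx", "cy", "cz")])
    for (i in seq_len(nrow(refs))) {
      d2 <- colSums((t(cc) - refs[i, ])^2)
      j <- which.min(d2)
      if (d2[j] <= box_radius^2)
        masses[i] <- voxels_to_mass(comp$voxel_count[j], vol$voxel_size)
    }
    if (!any(is.finite(masses))) next
    mean_mass <- mean(masses, na.rm = TRUE)
    if (mean_mass >= target_mass) {
      return(structure(thr, reference_masses = masses,
                       mean_mass = mean_mass))
    }
  }
  ng_error(sprintf(
    "mean reference mass never reached %.3g Da down to threshold %.2f",
    target_mass, minimum), "ng_calibration_failure")
}

#' Segment a volume into mass objects
#'
#' Binarizes the volume at `threshold`, extracts 26-connected components,
#' and converts each to a mass object: centroid (mean voxel coordinate,
#' 0-based), voxel count, mass via [voxels_to_mass()], and distance to the
#' fitted nucleolar center normalized by the fitted radius. Components
#' smaller than `min_voxels` are discarded (their total voxel count is
#' reported in the `discarded_voxels` attribute).
#'
#' @param vol A [voxel_volume()].
#' @param threshold Binarization threshold (same units as the volume).
#' @param sphere A `sphere_fit` (or any list with `center` and `radius`).
#' @param min_voxels Minimum component size in voxels (default 2).
#' @return A data.frame of class `mass_objects`: centroid, voxel_count,
#'   mass (Da), normalized_distance.
#' @export
segment_objects <- function(vol, threshold, sphere, min_voxels = 2L) {
  assert_volume(vol)
  ng_stopifnot(is.finite(threshold), "threshold must be finite")
  ng_stopifnot(is.numeric(sphere$radius) && sphere$radius > 0,
               "sphere must carry a positive radius")
  comp <- segment_components(vol, threshold, min_voxels = min_voxels)
  dist <- sqrt((comp$cx - sphere$center[1])^2 +
               (comp$cy - sphere$center[2])^2 +
               (comp$cz - sphere$center[3])^2)
  out <- data.frame(cx = comp$cx, cy = comp$cy, cz = comp$cz,
                    voxel_count = comp$voxel_count,
                    mass = voxels_to_mass(comp$voxel_count, vol$voxel_size),
                    normalized_distance = dist / sphere$radius)
  attr(out, "discarded_voxels") <- attr(comp, "discarded_voxels")
  class(out) <- c("mass_objects", "data.frame")
  out
}

#' Radial mass profile (mean object mass per distance bin)
#'
#' Groups objects by normalized distance and reports the arithmetic mean
#' object mass and the object count per bin. Bins with no objects have
#' count 0 and an undefined (NA) mean, not zero.
#'
#' @param objects A `mass_objects` data.frame from [segment_objects()].
#' @param bin_width Distance bin width (normalized units, default 0.05).
#' @return A data.frame with `bin_low`, `bin_high`, `mean_mass`, `count`.
#' @export
mass_profile_1d <- function(objects, bin_width = 0.05) {
  if (!nrow(objects))
    ng_error("no objects to profile", "ng_degenerate_input")
  dmax <- max(objects$normalized_distance)
  edges <- seq(0, (floor(dmax / bin_width) + 1) * bin_width, by = bin_width)
  bin <- findInterval(objects$normalized_distance, edges,
                      rightmost.closed = TRUE)
  nb <- length(edges) - 1L
  count <- tabulate(bin, nbins = nb)
  total <- rowsum(objects$mass, factor(bin, levels = seq_len(nb)))[, 1]
  mean_mass <- ifelse(count > 0, total / pmax(count, 1), NA_real_)
  data.frame(bin_low = edges[-length(edges)], bin_high = edges[-1],
             mean_mass = mean_mass, count = count)
}

#' Two-dimensional mass-vs-distance spectrum
#'
#' Total segmented protein mass per (mass, normalized distance) bin. The
#' grand sum over all cells equals the total mass of the input objects
#' exactly.
#'
#' @param objects A `mass_objects` data.frame.
#' @param mass_bin Mass bin width in Da (default 0.25 MDa).
#' @param dist_bin Distance bin width (normalized, default 0.05).
#' @return A list of class `mass_distance_histogram`: `mass_edges`,
#'   `dist_edges`, and `density` (matrix, mass bins x distance bins, Da).
#' @export
mass_distance_histogram_2d <- function(objects, mass_bin = 2.5e5,
                                       dist_bin = 0.05) {
  if (!nrow(objects))
    ng_error("no objects to histogram", "ng_degenerate_input")
  m_edges <- seq(0, (floor(max(objects$mass) / mass_bin) + 1) * mass_bin,
                 by = mass_bin)
  d_edges <- seq(0, (floor(max(objects$normalized_distance) / dist_bin) + 1) *
                   dist_bin, by = dist_bin)
  mi <- findInterval(objects$mass, m_edges, rightmost.closed = TRUE)
  di <- findInterval(objects$normalized_distance, d_edges,
                     rightmost.closed = TRUE)
  density <- matrix(0, length(m_edges) - 1L, length(d_edges) - 1L)
  for (i in seq_len(nrow(objects)))
    density[mi[i], di[i]] <- density[mi[i], di[i]] + objects$mass[i]
  structure(list(mass_edges = m_edges, dist_edges = d_edges,
                 density = density),
            class = "mass_distance_histogram")
}
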