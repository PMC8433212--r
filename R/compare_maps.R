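# Resample a volume onto a target voxel size (trilinear, about the map
# center), keeping the physical extent.
resample_volume <- function(vol, target_voxel_size) {
  if (abs(vol$voxel_size - target_voxel_size) < 1e-9) return(vol)
  d <- dim(vol$data)
  scale <- target_voxel_size / vol$voxel_size
  nd <- pmax(2L, as.integer(round(d / scale)))
  g <- grid_coords(nd)
  ctr_new <- (nd - 1) / 2
  ctr_old <- (d - 1) / 2
  src <- (g - ctr_new) * scale + ctr_old
  voxel_volume(array(trilinear_sample(vol$data, src, fill = mean(vol$data)),
                     dim = nd),
               voxel_size = target_voxel_size)
}

# Gaussian low-pass to a nominal resolution (Angstrom): half-amplitude at
# spatial frequency 1/resolution.
lowpass_to_resolution <- function(vol, resolution) {
  sigma_ang <- resolution * sqrt(log(2) / 2) / pi
  gaussian_filter_volume(vol, sigma = sigma_ang / vol$voxel_size)
}

masked_ncc <- function(a, b, mask = NULL) {
  if (is.null(mask)) mask <- rep(TRUE, length(a))
  av <- a[mask]; bv <- b[mask]
  av <- av - mean(av); bv <- bv - mean(bv)
  den <- sqrt(sum(av^2) * sum(bv^2))
  if (den == 0) return(0)
  sum(av * bv) / den
}

# Best integer-shift alignment of b onto a by FFT cross-correlation
# (circular); returns the aligned array.
align_translation <- function(a, b) {
  d <- dim(a)
  cc <- Re(stats::fft(stats::fft(a) * Conj(stats::fft(b)), inverse = TRUE))
  # sign-invariant: contrast-inverted maps align at their |correlation| peak
  peak <- which.max(abs(cc)) - 1
  sh <- c(peak %% d[1], (peak %/% d[1]) %% d[2], peak %/% (d[1] * d[2]))
  sh <- ifelse(sh > d / 2, sh - d, sh)
  g <- grid_coords(d)
  array(trilinear_sample(b, g - sh, fill = mean(b)), dim = d)
}

#' Compare two density maps by aligned normalized cross-correlation
#'
#' Resamples both maps to a common voxel size (the coarser of the two),
#' low-pass filters them to the stated resolution, globally aligns map B
#' onto map A by a coarse-to-fine exhaustive ZYZ Euler grid search (coarse
#' step `angle_step`, local refinement at `refine_step`) combined with
#' FFT translational alignment, and reports the masked normalized
#' cross-correlation of the aligned pair. Alignment maximizes the absolute
#' correlation (so contrast-inverted maps align at their true pose and
#' report a negative coefficient); the returned `ncc` keeps its sign.
#'
#' @param map_a,map_b [voxel_volume()]s of comparable physical extent.
#' @param resolution Comparison resolution in Angstrom (>= 2 x the coarser
#'   voxel size).
#' @param mask Optional logical array in map A's resampled grid.
#' @param angle_step,refine_step Rotation grid steps in degrees.
#' @return A list with `ncc`, `best_rotation` (3x3 matrix) and
#'   `best_angles` (ZYZ Euler angles, degrees).
#' @export
compare_maps <- function(map_a, map_b, resolution = 30, mask = NULL,
                         angle_step = 30, refine_step = 10) {
  assert_volume(map_a); assert_volume(map_b)
  vs <- max(map_a$voxel_size, map_b$voxel_size)
  if (resolution < 2 * vs)
    ng_error("resolution must be at least twice the coarser voxel size",
             "ng_invalid_argument")
  ext_a <- dim(map_a$data) * map_a$voxel_size
  ext_b <- dim(map_b$data) * map_b$voxel_size
  if (any(pmax(ext_a, ext_b) / pmin(ext_a, ext_b) > 2))
    ng_error("map physical extents differ by more than 2x",
             "ng_extent_mismatch")
  a <- lowpass_to_resolution(resample_volume(map_a, vs), resolution)
  b <- lowpass_to_resolution(resample_volume(map_b, vs), resolution)
  # put b on a's grid if shapes differ after resampling
  if (!identical(dim(a$data), dim(b$data))) {
    da <- dim(a$data); db <- dim(b$data)
    g <- grid_coords(da)
    src <- g - (da - 1) / 2 + (db - 1) / 2
    b$data <- array(trilinear_sample(b$data, src, fill = mean(b$data)),
                    dim = da)
  }
  score_rotation <- function(ang_deg) {
    R <- euler_zyz_matrix(ang_deg[1] * pi / 180, ang_deg[2] * pi / 180,
                          ang_deg[3] * pi / 180)
    rb <- rotate_array(b$data, R, fill = mean(b$data))
    aligned <- align_translation(a$data, rb)
    list(ncc = masked_ncc(a$data, aligned, mask), R = R, aligned = aligned)
  }
  coarse <- expand.grid(phi = seq(0, 360 - angle_step, by = angle_step),
                        theta = seq(0, 180, by = angle_step),
                        psi = seq(0, 360 - angle_step, by = angle_step))
  # degenerate theta: psi redundant at poles; keep psi = 0 rows only
  coarse <- coarse[!(coarse$theta %in% c(0, 180)) | coarse$psi == 0, ]
  best <- list(ncc = 0)
  best_ang <- c(0, 0, 0)
  for (r in seq_len(nrow(coarse))) {
    ang <- as.numeric(coarse[r, ])
    res <- score_rotation(ang)
    if (abs(res$ncc) > abs(best$ncc)) { best <- res; best_ang <- ang }
  }
  if (refine_step < angle_step) {
    offs <- seq(-angle_step + refine_step, angle_step - refine_step,
                by = refine_step)
    fine <- expand.grid(dphi = offs, dtheta = offs, dpsi = offs)
    for (r in seq_len(nrow(fine))) {
      ang <- best_ang + as.numeric(fine[r, ])
      res <- score_rotation(ang)
      if (abs(res$ncc) > abs(best$ncc)) { best <- res; best_ang <- ang }
    }
  }
  list(ncc = best$ncc, best_rotation = best$R, best_angles = best_ang)
}
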