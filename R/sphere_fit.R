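#' Algebraic least-squares sphere fit
#'
#' Fits a sphere to 3D points by linearizing x^2+y^2+z^2 = 2 c.x + (r^2 -
#' |c|^2) and solving the normal equations. This is the single fitting step
#' inside the iterated robust fit; on noise-free spherical data it agrees
#' with the geometric (distance-minimizing) fit to machine precision.
#'
#' @param points Numeric n x 3 matrix of positions (voxels), n >= 4 and not
#'   coplanar.
#' @return A list with `center` (length 3), `radius`, and `rms_residual`
#'   (RMS of point-to-surface distances, voxels).
#' @export
fit_sphere_lsq <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 4)
    ng_error("sphere fitting needs at least 4 points", "ng_too_few_points")
  A <- cbind(2 * points, 1)
  b <- rowSums(points^2)
  qr_A <- qr(A)
  if (qr_A$rank < 4)
    ng_error("degenerate point configuration (coplanar or rank-deficient)",
             "ng_degenerate_geometry")
  beta <- qr.coef(qr_A, b)
  center <- beta[1:3]
  r2 <- beta[4] + sum(center^2)
  if (!is.finite(r2) || r2 <= 0)
    ng_error("degenerate point configuration (non-positive fitted radius)",
             "ng_degenerate_geometry")
  radius <- sqrt(r2)
  dist <- sqrt(rowSums((points - rep(center, each = nrow(points)))^2))
  list(center = unname(center), radius = unname(radius),
       rms_residual = sqrt(mean((dist - radius)^2)))
}

#' Robust sphere fit with iterated +/- 1 SD outlier rejection
#'
#' Starting from all points, repeatedly: fit the sphere to the current
#' inliers, compute every point's distance to the fitted center, and define
#' the next inlier set as the points whose distance lies within mean +/- 1
#' SD of the current inliers' distance distribution. Iteration stops when
#' the inlier set is unchanged (exact fixed point), when it would shrink
#' below 4 points (recorded as `collapsed`), or at `max_iter`. The returned
#' fit is the post-rejection iteration that retained the most points among
#' the settled iterations — those whose RMS residual is within 3x of the
#' following iteration's, i.e. whose fit no longer changes materially under
#' further rejection (ties: smaller RMS residual, then earlier iteration).
#' Rejection is two-sided and non-monotone: previously removed points
#' re-enter if they fall inside the new band.
#'
#' @param points Numeric n x 3 matrix (n >= 4).
#' @param max_iter Maximum number of fit/reject iterations.
#' @return A `sphere_fit` object: `center`, `radius`, `rms_residual`,
#'   `inlier_indices`, `n_iterations`, and `history` (per-iteration center,
#'   radius, retained count, rms).
#' @export
fit_sphere_robust <- function(points, max_iter = 50L) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < 4)
    ng_error("sphere fitting needs at least 4 points", "ng_too_few_points")
  inliers <- seq_len(n)
  history <- list()
  seen <- character()
  collapsed <- FALSE
  for (it in seq_len(max_iter)) {
    fit <- fit_sphere_lsq(points[inliers, , drop = FALSE])
    history[[it]] <- list(center = fit$center, radius = fit$radius,
                          rms_residual = fit$rms_residual,
                          retained = length(inliers),
                          inlier_indices = inliers)
    d_all <- sqrt(rowSums((points - rep(fit$center, each = n))^2))
    d_in <- d_all[inliers]
    band <- mean(d_in) + c(-1, 1) * stats::sd(d_in)
    tol <- 1e-9 * (1 + mean(d_in))   # guards the noise-free fixed point
    new_inliers <- which(d_all >= band[1] - tol & d_all <= band[2] + tol)
    key <- paste(new_inliers, collapse = ",")
    if (identical(new_inliers, inliers) || key %in% seen) break
    if (length(new_inliers) < 4) { collapsed <- TRUE; break }
    seen <- c(seen, paste(inliers, collapse = ","))
    inliers <- new_inliers
  }
  # Selection among the post-rejection fits (the first fit uses every
  # point, so it would trivially maximize the retained count). A fit is a
  # candidate once it has settled: further rejection no longer collapses
  # its residual scale (rms within 3x of the next iteration's), i.e. the
  # fit has stopped changing in any material way. Among settled fits the
  # one retaining the most points wins.
  retained <- vapply(history, `[[`, integer(1), "retained")
  rms <- vapply(history, `[[`, numeric(1), "rms_residual")
  K <- length(history)
  eligible <- if (K > 1) seq_along(history)[-1] else 1L
  settled <- vapply(eligible, function(k)
    k == K || rms[k] <= 3 * rms[k + 1], logical(1))
  if (any(settled)) eligible <- eligible[settled]
  best <- eligible[order(-retained[eligible], rms[eligible], eligible)[1]]
  res <- history[[best]]
  structure(list(center = res$center, radius = res$radius,
                 rms_residual = res$rms_residual,
                 inlier_indices = res$inlier_indices,
                 n_iterations = length(history),
                 best_iteration = best,
                 collapsed = collapsed,
                 history = history),
            class = "sphere_fit")
}

#' @export
print.sphere_fit <- function(x, ...) {
  cat(sprintf(
    "<sphere_fit> center (%.2f, %.2f, %.2f), radius %.2f voxels\n",
    x$center[1], x$center[2], x$center[3], x$radius))
  cat(sprintf("  %d/%d points retained after %d iteration(s), rms %.3f\n",
              length(x$inlier_indices),
              x$history[[1]]$retained, x$n_iterations, x$rms_residual))
  invisible(x)
}

#' Fit nucleolar spheres tomogram by tomogram
#'
#' Runs the robust fit independently on the pooled pre-ribosome positions
#' of each tomogram (both precursor classes together). Tomograms with too
#' few particles, or whose fit fails, are reported in `failed` rather than
#' aborting the batch; a minimum retained-inlier count filters tomograms
#' without enough of the nucleolar ring to constrain a sphere.
#'
#' @param table A [particle_table()].
#' @param max_iter Per-tomogram iteration cap.
#' @param min_inliers Minimum retained inliers for a fit to be accepted.
#' @return A list with `fits` (named list of `sphere_fit` by tomogram_id)
#'   and `failed` (named character vector of failure reasons).
#' @export
fit_spheres_per_tomogram <- function(table, max_iter = 50L,
                                     min_inliers = 10L) {
  stopifnot(nrow(table) > 0)
  ids <- unique(table$tomogram_id)
  fits <- list(); failed <- character()
  for (id in ids) {
    pts <- as.matrix(table[table$tomogram_id == id, c("x", "y", "z")])
    res <- tryCatch(fit_sphere_robust(pts, max_iter = max_iter),
                    ng_error = function(e) conditionMessage(e))
    if (is.character(res)) {
      failed[id] <- res
    } else if (length(res$inlier_indices) < min_inliers) {
      failed[id] <- sprintf("only %d inliers retained (minimum %d)",
                            length(res$inlier_indices), min_inliers)
    } else {
      fits[[id]] <- res
    }
  }
  list(fits = fits, failed = failed)
}

#' Tabulate per-tomogram sphere fits
#'
#' @param fit_map Result of [fit_spheres_per_tomogram()].
#' @param voxel_size Voxel size in Angstrom used to report radii in nm.
#' @return A data.frame with one row per fitted tomogram.
#' @export
sphere_fit_table <- function(fit_map, voxel_size = 13.68) {
  fits <- fit_map$fits
  if (!length(fits))
    return(data.frame(tomogram_id = character(), cx = numeric(),
                      cy = numeric(), cz = numeric(),
                      radius_voxels = numeric(), radius_nm = numeric(),
                      n_inliers = integer(), n_iterations = integer()))
  data.frame(tomogram_id = names(fits),
             cx = vapply(fits, function(f) f$center[1], 0),
             cy = vapply(fits, function(f) f$center[2], 0),
             cz = vapply(fits, function(f) f$center[3], 0),
             radius_voxels = vapply(fits, `[[`, 0, "radius"),
             radius_nm = vapply(fits, `[[`, 0, "radius") * voxel_size / 10,
             n_inliers = vapply(fits, function(f)
               length(f$inlier_indices), 0L),
             n_iterations = vapply(fits, `[[`, 0L, "n_iterations"),
             row.names = NULL, stringsAsFactors = FALSE)
}
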