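#' Standardize a volume to zero mean and unit standard deviation
#'
#' Standardization uses the population convention (divisor N). Tomograms are
#' standardized this way before threshold calibration so that binarization
#' thresholds are expressed in units of the volume's global contrast.
#'
#' @param vol A [voxel_volume()] with at least 2 voxels and nonzero variance.
#' @return A [voxel_volume()] with mean 0 and SD 1 (within 1e-6).
#' @export
normalize_volume <- function(vol) {
  assert_volume(vol)
  n <- length(vol$data)
  if (n < 2)
    ng_error("volume must have at least 2 voxels", "ng_degenerate_input")
  mu <- mean(vol$data)
  sigma <- sqrt(sum((vol$data - mu)^2) / n)
  if (sigma == 0)
    ng_error("cannot normalize a constant volume", "ng_degenerate_input")
  vol$data <- (vol$data - mu) / sigma
  vol
}

# Mirror-with-edge-repeat reflection of 0-based indices into [0, n)
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(0L, length(i)))
  period <- 2L * n
  i <- i %% period
  i[i < 0] <- i[i < 0] + period
  ifelse(i >= n, period - 1L - i, i)
}

# Dense smoothing operator along one axis with reflective boundaries;
# rows sum to 1 exactly.
gaussian_axis_operator <- function(n, sigma) {
  r <- max(1L, as.integer(ceiling(4 * sigma)))
  w <- exp(-((-r:r)^2) / (2 * sigma^2))
  w <- w / sum(w)
  K <- matrix(0, n, n)
  for (k in seq_along(w)) {
    off <- k - r - 1L
    j <- reflect_index((0:(n - 1L)) + off, n)
    idx <- cbind(1:n, j + 1L)
    K[idx] <- K[idx] + w[k]
  }
  K
}

#' Gaussian smoothing of a volume
#'
#' Separable 3D Gaussian filter with reflective boundary handling, applied
#' before density segmentation (default sigma of 3 voxels at the bin-4
#' working scale). The kernel is normalized, so the total density of
#' interior features is conserved.
#'
#' @param vol A [voxel_volume()].
#' @param sigma Kernel standard deviation in voxels (>= 0; 0 is identity).
#' @return The filtered [voxel_volume()].
#' @export
gaussian_filter_volume <- function(vol, sigma = 3) {
  assert_volume(vol)
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma < 0)
    ng_error("`sigma` must be a single non-negative number",
             "ng_invalid_argument")
  if (sigma == 0) return(vol)
  arr <- vol$data
  # smooth the current first axis, then rotate axes; three rotations
  # restore the original order
  for (pass in 1:3) {
    d <- dim(arr)
    K <- gaussian_axis_operator(d[1], sigma)
    arr <- array(K %*% matrix(arr, nrow = d[1]), dim = d)
    arr <- aperm(arr, c(2, 3, 1))
  }
  vol$data <- arr
  vol
}
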