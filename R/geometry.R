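# Geometry helpers shared by reference construction, classification and
# map comparison: trilinear resampling and 3D rotations. All coordinates
# are 0-based voxel coordinates with voxel centers at integers.

# Sample `arr` at 0-based coordinates `coords` (3 x N matrix) by trilinear
# interpolation; points outside the grid return `fill`.
trilinear_sample <- function(arr, coords, fill = 0) {
  d <- dim(arr)
  x <- coords[1, ]; y <- coords[2, ]; z <- coords[3, ]
  x0 <- floor(x); y0 <- floor(y); z0 <- floor(z)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  out <- rep(fill, length(x))
  ok <- x0 >= -1 & x0 <= d[1] - 1 & y0 >= -1 & y0 <= d[2] - 1 &
        z0 >= -1 & z0 <= d[3] - 1
  if (!any(ok)) return(out)
  at <- function(ix, iy, iz) {
    # corner lookup with out-of-grid corners contributing `fill`
    inside <- ix >= 0 & ix < d[1] & iy >= 0 & iy < d[2] & iz >= 0 & iz < d[3]
    v <- rep(fill, length(ix))
    idx <- 1 + ix[inside] + d[1] * (iy[inside] + d[2] * iz[inside])
    v[inside] <- arr[idx]
    v
  }
  x0k <- x0[ok]; y0k <- y0[ok]; z0k <- z0[ok]
  fxk <- fx[ok]; fyk <- fy[ok]; fzk <- fz[ok]
  v000 <- at(x0k,     y0k,     z0k)
  v100 <- at(x0k + 1, y0k,     z0k)
  v010 <- at(x0k,     y0k + 1, z0k)
  v110 <- at(x0k + 1, y0k + 1, z0k)
  v001 <- at(x0k,     y0k,     z0k + 1)
  v101 <- at(x0k + 1, y0k,     z0k + 1)
  v011 <- at(x0k,     y0k + 1, z0k + 1)
  v111 <- at(x0k + 1, y0k + 1, z0k + 1)
  c00 <- v000 * (1 - fxk) + v100 * fxk
  c10 <- v010 * (1 - fxk) + v110 * fxk
  c01 <- v001 * (1 - fxk) + v101 * fxk
  c11 <- v011 * (1 - fxk) + v111 * fxk
  c0 <- c00 * (1 - fyk) + c10 * fyk
  c1 <- c01 * (1 - fyk) + c11 * fyk
  out[ok] <- c0 * (1 - fzk) + c1 * fzk
  out
}

# Intrinsic ZYZ Euler rotation matrix, angles in radians
euler_zyz_matrix <- function(phi, theta, psi) {
  rz <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3)
  ry <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3)
  rz(phi) %*% ry(theta) %*% rz(psi)
}

# Uniform random rotation via normalized Gaussian quaternion
random_rotation_matrix <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3)
}

# 0-based coordinates of every voxel of a grid, as a 3 x N matrix
grid_coords <- function(d) {
  t(as.matrix(expand.grid(x = 0:(d[1] - 1), y = 0:(d[2] - 1),
                          z = 0:(d[3] - 1))))
}

# Rotate a 3D array about its geometric center by rotation matrix R
# (voxel frame), resampling trilinearly.
rotate_array <- function(arr, R, fill = 0) {
  d <- dim(arr)
  ctr <- (d - 1) / 2
  g <- grid_coords(d)
  src <- t(R) %*% (g - ctr) + ctr   # pull-back: inverse rotation of targets
  array(trilinear_sample(arr, src, fill = fill), dim = d)
}
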