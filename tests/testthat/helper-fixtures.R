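# Shared fixture builders: everything is generated in code at test time.

# n points on (or near) a sphere surface; noise is isotropic Gaussian
# positional jitter in voxels
sphere_surface_points <- function(n, center = c(0, 0, 0), radius = 100,
                                  noise = 0) {
  u <- matrix(rnorm(3 * n), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  pts <- u * radius + rep(center, each = n)
  if (noise > 0) pts <- pts + matrix(rnorm(3 * n, 0, noise), ncol = 3)
  pts
}

# A volume containing discrete balls of given voxel radii at given 0-based
# centers (amplitude 1 on zero background)
ball_volume <- function(dim3, centers, radii, voxel_size = 13.68) {
  arr <- array(0, dim = dim3)
  g <- as.matrix(expand.grid(x = 0:(dim3[1] - 1), y = 0:(dim3[2] - 1),
                             z = 0:(dim3[3] - 1)))
  for (i in seq_len(nrow(centers))) {
    d2 <- (g[, 1] - centers[i, 1])^2 + (g[, 2] - centers[i, 2])^2 +
      (g[, 3] - centers[i, 3])^2
    arr[d2 <= radii[i]^2] <- 1
  }
  voxel_volume(arr, voxel_size = voxel_size)
}

# Small structured template: off-center blob pair, zero background
structured_template <- function(box = 11, voxel_size = 13.68) {
  g <- as.matrix(expand.grid(x = 0:(box - 1), y = 0:(box - 1),
                             z = 0:(box - 1)))
  c1 <- (box - 1) / 2 + c(-1.5, 0, 0)
  c2 <- (box - 1) / 2 + c(2, 1, -1)
  v <- exp(-rowSums((g - rep(c1, each = nrow(g)))^2) / 4) +
    0.7 * exp(-rowSums((g - rep(c2, each = nrow(g)))^2) / 3)
  voxel_volume(array(v, dim = c(box, box, box)), voxel_size = voxel_size)
}

# Insert template data into a volume with the template's (0-based) corner
# at `corner`
insert_template <- function(vol, tmpl_data, corner) {
  kd <- dim(tmpl_data)
  vol$data[corner[1] + 1:kd[1], corner[2] + 1:kd[2], corner[3] + 1:kd[3]] <-
    vol$data[corner[1] + 1:kd[1], corner[2] + 1:kd[2],
             corner[3] + 1:kd[3]] + tmpl_data
  vol
}
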