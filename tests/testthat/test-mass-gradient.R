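# Independent unit-conversion oracle, written out from first principles:
# (voxel_size in cm)^3 * density / (grams per Dalton)
oracle_mass <- function(nvox, voxel_ang)
  nvox * (voxel_ang * 1e-8)^3 * 1.3 / 1.66054e-24

test_that("voxel counts convert to Dalton masses at protein density", {
  expect_identical(voxels_to_mass(0, 13.68), 0)
  # one bin-4 voxel ~ 2004 Da
  expect_equal(voxels_to_mass(1, 13.68), oracle_mass(1, 13.68))
  expect_equal(voxels_to_mass(1, 13.68), 2004.5, tolerance = 1e-3)
  # 2245 voxels ~ the 4.5 MDa calibration target
  expect_equal(voxels_to_mass(2245, 13.68), 4.5e6, tolerance = 1e-3)
  expect_error(voxels_to_mass(-1, 13.68), class = "ng_invalid_argument")
})

test_that("discrete balls hold ~ (4/3) pi k^3 voxels for k >= 6", {
  for (k in c(6, 8, 11)) {
    v <- ball_volume(c(2 * k + 9, 2 * k + 9, 2 * k + 9),
                     matrix(rep(k + 4, 3), 1), k)
    expect_lt(abs(sum(v$data) - 4 / 3 * pi * k^3) / (4 / 3 * pi * k^3),
              0.05)
  }
})

test_that("segmentation yields correct components, masses and distances", {
  sphere <- list(center = c(20, 20, 20), radius = 15)
  v <- ball_volume(c(48, 48, 48), rbind(c(20, 20, 35), c(38, 38, 10)),
                   c(4, 3))
  obj <- segment_objects(v, 0.5, sphere)
  expect_equal(nrow(obj), 2)
  expect_setequal(obj$voxel_count,
                  c(sum(ball_volume(c(48, 48, 48),
                                    matrix(c(20, 20, 35), 1), 4)$data),
                    sum(ball_volume(c(48, 48, 48),
                                    matrix(c(38, 38, 10), 1), 3)$data)))
  expect_equal(obj$mass, voxels_to_mass(obj$voxel_count, v$voxel_size))

  # ball centered on the fitted surface -> normalized distance 1.000
  on_surface <- obj[which.min(abs(obj$cx - 20)), ]
  expect_equal(on_surface$normalized_distance, 1, tolerance = 0.01)

  # min-size filtering accounts for discarded voxels
  v$data[c(1, 2)] <- 1   # a 2-voxel blob at the corner
  v$data[48 * 48 * 48] <- 1  # a single-voxel blob
  obj2 <- segment_objects(v, 0.5, sphere, min_voxels = 2L)
  expect_equal(nrow(obj2), 3)
  expect_equal(attr(obj2, "discarded_voxels"), 1L)
})

test_that("segmented masses track ground truth in a rendered scenario", {
  # well-separated particles of known mass (no overlap), mild noise
  centers <- as.matrix(expand.grid(x = c(20, 60), y = c(20, 60),
                                   z = c(20, 60)))
  masses <- seq(5e5, 2.6e6, length.out = nrow(centers))
  cfg <- scenario_config(sphere_center = c(40, 40, 40), sphere_radius = 30,
                         classes = list(), background_spectrum = NULL,
                         surface_spike = NULL, noise_sd = 0.1,
                         grid_dim = c(80, 80, 80), seed = 31)
  truth <- list(center = cfg$sphere_center, radius = cfg$sphere_radius,
                particles = data.frame(tomogram_id = "t", kind = "bg",
                                       class_label = NA_integer_,
                                       x = centers[, 1], y = centers[, 2],
                                       z = centers[, 3], mass = masses,
                                       r_norm = 1))
  tab <- particle_table(rep("t", nrow(centers)), centers[, 1],
                        centers[, 2], centers[, 3])
  vol <- generate_tomogram_volume(cfg, tab, truth)
  amp <- attr(vol, "foreground_amplitude")
  obj <- segment_objects(vol, amp / 2, list(center = c(40, 40, 40),
                                            radius = 30))
  big <- obj[obj$voxel_count >= 100, ]
  expect_equal(nrow(big), nrow(centers))
  for (i in seq_len(nrow(big))) {
    d2 <- (truth$particles$x - big$cx[i])^2 +
      (truth$particles$y - big$cy[i])^2 +
      (truth$particles$z - big$cz[i])^2
    expect_lt(abs(big$mass[i] - truth$particles$mass[which.min(d2)]) /
                truth$particles$mass[which.min(d2)], 0.1)
  }
})

test_that("raising the threshold is monotone in voxel counts", {
  set.seed(32)
  v <- voxel_volume(array(rnorm(24^3), dim = c(24, 24, 24)), voxel_size = 1)
  sphere <- list(center = c(12, 12, 12), radius = 10)
  total <- function(t) sum(segment_objects(v, t, sphere,
                                           min_voxels = 1L)$voxel_count)
  thresholds <- c(0.5, 1, 1.5, 2)
  totals <- vapply(thresholds, total, 0)
  expect_true(all(diff(totals) <= 0))
})

test_that("threshold calibration reaches the reference target mass", {
  # 20 balls of true mass 4.5 MDa in noise; calibrated threshold must
  # measure their mean mass within 10%
  centers <- as.matrix(expand.grid(x = c(20, 50, 80, 110, 140),
                                   y = c(30, 90), z = c(30, 90)))
  cfg <- scenario_config(sphere_center = c(80, 60, 60), sphere_radius = 40,
                         classes = list(), background_spectrum = NULL,
                         surface_spike = NULL, noise_sd = 0.2,
                         grid_dim = c(160, 120, 120), seed = 33)
  truth <- list(center = cfg$sphere_center, radius = cfg$sphere_radius,
                particles = data.frame(tomogram_id = "t", kind = "ref",
                                       class_label = NA_integer_,
                                       x = centers[, 1], y = centers[, 2],
                                       z = centers[, 3], mass = 4.5e6,
                                       r_norm = 0))
  refs <- particle_table(rep("t", nrow(centers)), centers[, 1],
                         centers[, 2], centers[, 3])
  vol <- generate_tomogram_volume(cfg, refs, truth)
  nvol <- normalize_volume(vol)
  thr <- calibrate_threshold(nvol, refs, target_mass = 4.5e6,
                             box_radius = 10)
  expect_equal(attr(thr, "mean_mass"), 4.5e6, tolerance = 0.1)
  expect_true(all(is.finite(attr(thr, "reference_masses"))))

  # references already above target at the starting threshold: the start
  # is returned
  thr2 <- calibrate_threshold(nvol, refs, target_mass = 1e5,
                              box_radius = 10,
                              start = as.numeric(thr) + 0.2)
  expect_equal(as.numeric(thr2), as.numeric(thr) + 0.2)

  # an empty volume cannot reach any positive target
  empty <- voxel_volume(array(rnorm(40^3, 0, 0.01), dim = c(40, 40, 40)),
                        voxel_size = 13.68)
  refs5 <- particle_table(rep("t", 5), c(10, 20, 30, 10, 20),
                          c(10, 20, 30, 30, 10), c(20, 20, 20, 20, 20))
  expect_error(calibrate_threshold(empty, refs5, target_mass = 4.5e6,
                                   minimum = 3),
               class = "ng_calibration_failure")
})

test_that("1D mass profile bins objects by normalized distance", {
  obj <- data.frame(cx = 0, cy = 0, cz = 0,
                    voxel_count = c(10, 10, 10),
                    mass = c(1e6, 1e6, 1e6),
                    normalized_distance = c(0.5, 0.52, 0.51))
  prof <- mass_profile_1d(obj, bin_width = 0.05)
  occupied <- prof[prof$count > 0, ]
  expect_equal(nrow(occupied), 1)
  expect_equal(occupied$mean_mass, 1e6)
  expect_equal(occupied$count, 3)
  # empty bins report count 0 and undefined mean
  expect_true(all(is.na(prof$mean_mass[prof$count == 0])))
})

test_that("mass spike at the surface dominates the outer profile bins", {
  # background up to 2.5 MDa everywhere, 3-5.5 MDa spike at the surface:
  # the maximum mean-mass bin must sit at the nucleolar surface
  cfg <- scenario_config(sphere_center = c(0, 0, 0), sphere_radius = 200,
                         classes = list(),
                         background_spectrum = list(mass_min = 2e5,
                                                    mass_max = 2.5e6,
                                                    count = 2000),
                         surface_spike = list(mass_min = 3e6,
                                              mass_max = 5.5e6,
                                              count = 400,
                                              shell_mean = 1.0,
                                              shell_sd = 0.02),
                         seed = 34)
  g <- generate_particle_positions(cfg)
  tp <- g$truth$particles
  obj <- data.frame(cx = tp$x, cy = tp$y, cz = tp$z, voxel_count = 1,
                    mass = tp$mass, normalized_distance = tp$r_norm)
  prof <- mass_profile_1d(obj, bin_width = 0.05)
  peak <- prof[which.max(prof$mean_mass), ]
  expect_gte(peak$bin_low, 0.9)
  expect_lte(peak$bin_high, 1.1)

  # 2D histogram: the 3-5.5 MDa rows concentrate at distance ~ 1
  h2 <- mass_distance_histogram_2d(obj, mass_bin = 2.5e5, dist_bin = 0.05)
  spike_rows <- which(h2$mass_edges[-1] > 3e6 &
                        h2$mass_edges[-length(h2$mass_edges)] < 5.5e6)
  row_mass <- colSums(h2$density[spike_rows, , drop = FALSE])
  mids <- (h2$dist_edges[-1] + h2$dist_edges[-length(h2$dist_edges)]) / 2
  centroid <- sum(row_mass * mids) / sum(row_mass)
  expect_gte(centroid, 0.9)
  expect_lte(centroid, 1.1)
})

test_that("2D histogram conserves total mass exactly", {
  set.seed(35)
  obj <- data.frame(cx = 0, cy = 0, cz = 0, voxel_count = 1,
                    mass = runif(200, 1e5, 6e6),
                    normalized_distance = runif(200, 0, 1.4))
  h <- mass_distance_histogram_2d(obj)
  expect_equal(sum(h$density), sum(obj$mass), tolerance = 1e-12)

  one <- obj[1, , drop = FALSE]
  h1 <- mass_distance_histogram_2d(one)
  expect_identical(sum(h1$density > 0), 1L)
  expect_identical(max(h1$density), one$mass)
})
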