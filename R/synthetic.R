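#' Configure a synthetic nucleolar scenario
#'
#' Describes a ground-truthed synthetic tomogram emulating the study system:
#' a nucleolus of ~600 nm radius decorated with pre-ribosome classes in
#' radial shells, a background field of smaller nuclear particles with
#' masses up to ~2.5 MDa, a surface spike of large 3-5.5 MDa complexes, and
#' an optional lamella slab that truncates the sphere the way FIB-milled
#' lamellae cut nucleoli at arbitrary angles and heights.
#'
#' Defaults encode the study conditions: sphere radius 438 voxels
#' (599 nm at the 13.68 A/voxel working scale), three particle classes in
#' shells at normalized radii 0.85 / 0.95 / 1.00 (SD 0.05, 500 particles
#' each, masses in the 3-5.5 MDa pre-ribosome range), a uniform-in-volume
#' background up to 2.5 MDa, and a 3-5.5 MDa surface spike.
#'
#' @param sphere_center Numeric length-3, voxels (0-based frame).
#' @param sphere_radius Positive radius in voxels.
#' @param classes List of per-class specs: `label`, `count`, `shell_mean`,
#'   `shell_sd` (normalized radii), optional `mass_min`/`mass_max` in Da.
#' @param background_spectrum List with `mass_min`, `mass_max` (Da), `count`;
#'   positions uniform in the sphere volume.
#' @param surface_spike List with `mass_min`, `mass_max`, `count`,
#'   `shell_mean`, `shell_sd`.
#' @param slab Optional list with `normal` (3-vector), `offset` (voxels,
#'   along the unit normal from the coordinate origin) and `thickness`
#'   (voxels); particles outside the slab are rejected and redrawn.
#' @param noise_sd Additive Gaussian noise SD for rendered volumes
#'   (arbitrary density units).
#' @param voxel_size Voxel size in Angstrom for rendered volumes.
#' @param grid_dim Integer length-3 grid for rendered volumes, or NULL for
#'   position-only scenarios.
#' @param tomogram_id,condition Identifiers stamped on generated particles.
#' @param seed Integer seed; all generation is deterministic given it.
#' @return A validated list of class `scenario_config`.
#' @export
scenario_config <- function(sphere_center = c(512, 512, 512),
                            sphere_radius = 438,
                            classes = list(
                              list(label = 1L, count = 500L,
                                   shell_mean = 0.85, shell_sd = 0.05),
                              list(label = 2L, count = 500L,
                                   shell_mean = 0.95, shell_sd = 0.05),
                              list(label = 3L, count = 500L,
                                   shell_mean = 1.00, shell_sd = 0.05)),
                            background_spectrum = list(mass_min = 2e5,
                                                       mass_max = 2.5e6,
                                                       count = 1500L),
                            surface_spike = list(mass_min = 3e6,
                                                 mass_max = 5.5e6,
                                                 count = 300L,
                                                 shell_mean = 1.0,
                                                 shell_sd = 0.05),
                            slab = NULL,
                            noise_sd = 0.25,
                            voxel_size = 13.68,
                            grid_dim = NULL,
                            tomogram_id = "tomo_1",
                            condition = "log",
                            seed = 1L) {
  ng_stopifnot(is.numeric(sphere_radius) && sphere_radius > 0,
               "sphere_radius must be positive")
  ng_stopifnot(length(sphere_center) == 3 && all(is.finite(sphere_center)),
               "sphere_center must be a finite 3-vector")
  for (cl in classes) {
    ng_stopifnot(cl$count >= 0, "class counts must be >= 0")
    ng_stopifnot(cl$shell_sd > 0, "shell_sd must be > 0")
  }
  for (blk in list(background_spectrum, surface_spike))
    if (!is.null(blk))
      ng_stopifnot(blk$mass_max >= blk$mass_min,
                   "mass_max must be >= mass_min")
  if (!is.null(slab)) {
    ng_stopifnot(length(slab$normal) == 3 && any(slab$normal != 0),
                 "slab normal must be a nonzero 3-vector")
    ng_stopifnot(slab$thickness > 0, "slab thickness must be positive")
  }
  structure(list(sphere_center = as.numeric(sphere_center),
                 sphere_radius = as.numeric(sphere_radius),
                 classes = classes,
                 background_spectrum = background_spectrum,
                 surface_spike = surface_spike,
                 slab = slab, noise_sd = noise_sd,
                 voxel_size = voxel_size, grid_dim = grid_dim,
                 tomogram_id = tomogram_id, condition = condition,
                 seed = as.integer(seed)),
            class = "scenario_config")
}

# Uniform directions on the unit sphere
runif_directions <- function(n) {
  v <- matrix(stats::rnorm(3 * n), nrow = 3)
  nrm <- sqrt(colSums(v^2))
  nrm[nrm == 0] <- 1
  v / rep(nrm, each = 3)
}

slab_keep <- function(p, slab) {
  if (is.null(slab)) return(rep(TRUE, ncol(p)))
  n <- slab$normal / sqrt(sum(slab$normal^2))
  abs(colSums(p * n) - slab$offset) <= slab$thickness / 2
}

# Draw `count` positions on a radial shell (or uniform in volume when
# shell_mean is NULL), rejecting draws outside the slab. Radial law:
# r = radius * Normal(shell_mean, shell_sd), redrawn until positive.
draw_population <- function(count, center, radius, shell_mean, shell_sd,
                            slab, max_rounds = 1000L) {
  if (count == 0) return(matrix(numeric(0), nrow = 3))
  kept <- matrix(numeric(0), nrow = 3)
  rounds <- 0L
  while (ncol(kept) < count && rounds < max_rounds) {
    m <- max(count - ncol(kept), 32L)
    if (is.null(shell_mean)) {
      r <- radius * stats::runif(m)^(1 / 3)
    } else {
      r <- radius * stats::rnorm(m, shell_mean, shell_sd)
      bad <- r <= 0
      while (any(bad)) {
        r[bad] <- radius * stats::rnorm(sum(bad), shell_mean, shell_sd)
        bad <- r <= 0
      }
    }
    p <- runif_directions(m) * rep(r, each = 3) + center
    p <- p[, slab_keep(p, slab), drop = FALSE]
    if (ncol(p)) kept <- cbind(kept, p)
    rounds <- rounds + 1L
  }
  if (ncol(kept) == 0)
    ng_error("slab does not intersect the particle shell: no position accepted within the retry budget",
             "ng_impossible_slab")
  short <- ncol(kept) < count
  if (short)
    warning(sprintf("slab rejection left %d of %d requested particles",
                    ncol(kept), count))
  structure(kept[, seq_len(min(count, ncol(kept))), drop = FALSE],
            short = short)
}

#' Generate ground-truthed particle positions for a scenario
#'
#' Draws each configured class on its radial shell (distance = radius x
#' Normal(shell_mean, shell_sd), redrawn until positive, direction uniform),
#' the background population uniform in the sphere volume, and the surface
#' spike on its shell; positions falling outside the lamella slab (when
#' configured) are rejected and redrawn. Deterministic under `cfg$seed`.
#'
#' @param cfg A [scenario_config()].
#' @return A list with `particles` (a [particle_table()] with class labels
#'   for shell classes, NA for background/spike) and `truth` (a list with
#'   `center`, `radius`, and a per-particle data.frame `particles` holding
#'   kind, true class, true mass in Da, position and normalized radius).
#' @export
generate_particle_positions <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  with_rng_seed(cfg$seed, {
    pos <- list(); kind <- list(); labl <- list(); mass <- list()
    for (cl in cfg$classes) {
      p <- draw_population(cl$count, cfg$sphere_center, cfg$sphere_radius,
                           cl$shell_mean, cl$shell_sd, cfg$slab)
      mmin <- if (is.null(cl$mass_min)) 3e6 else cl$mass_min
      mmax <- if (is.null(cl$mass_max)) 5.5e6 else cl$mass_max
      pos[[length(pos) + 1]] <- p
      kind[[length(kind) + 1]] <- rep("class", ncol(p))
      labl[[length(labl) + 1]] <- rep(as.integer(cl$label), ncol(p))
      mass[[length(mass) + 1]] <- stats::runif(ncol(p), mmin, mmax)
    }
    bg <- cfg$background_spectrum
    if (!is.null(bg) && bg$count > 0) {
      p <- draw_population(bg$count, cfg$sphere_center, cfg$sphere_radius,
                           NULL, NULL, cfg$slab)
      pos[[length(pos) + 1]] <- p
      kind[[length(kind) + 1]] <- rep("background", ncol(p))
      labl[[length(labl) + 1]] <- rep(NA_integer_, ncol(p))
      mass[[length(mass) + 1]] <- stats::runif(ncol(p), bg$mass_min,
                                               bg$mass_max)
    }
    sp <- cfg$surface_spike
    if (!is.null(sp) && sp$count > 0) {
      p <- draw_population(sp$count, cfg$sphere_center, cfg$sphere_radius,
                           sp$shell_mean, sp$shell_sd, cfg$slab)
      pos[[length(pos) + 1]] <- p
      kind[[length(kind) + 1]] <- rep("spike", ncol(p))
      labl[[length(labl) + 1]] <- rep(NA_integer_, ncol(p))
      mass[[length(mass) + 1]] <- stats::runif(ncol(p), sp$mass_min,
                                               sp$mass_max)
    }
    P <- if (length(pos)) do.call(cbind, pos) else matrix(numeric(0), 3)
    kind <- as.character(unlist(kind))
    labl <- as.integer(unlist(labl))
    mass <- as.numeric(unlist(mass))
    r_norm <- sqrt(colSums((P - cfg$sphere_center)^2)) / cfg$sphere_radius
    particles <- particle_table(rep(cfg$tomogram_id, ncol(P)),
                                P[1, ], P[2, ], P[3, ],
                                class_label = labl,
                                condition = cfg$condition,
                                provenance = "synthetic scenario")
    truth <- list(center = cfg$sphere_center, radius = cfg$sphere_radius,
                  particles = data.frame(tomogram_id = rep(cfg$tomogram_id,
                                                           ncol(P)),
                                         kind = kind, class_label = labl,
                                         x = P[1, ], y = P[2, ], z = P[3, ],
                                         mass = mass, r_norm = r_norm,
                                         stringsAsFactors = FALSE))
    list(particles = particles, truth = truth)
  })
}

#' Render a scenario as a density volume
#'
#' Each particle becomes a uniform-density discrete ball whose voxel count
#' equals its true mass divided by the per-voxel mass at the given voxel
#' size and protein density 1.3 g/cm^3 (see [voxels_to_mass()]); the ball is
#' the set of that many grid voxels nearest the particle center, so rendered
#' voxel counts match the mass conversion to within discretization ties.
#' Foreground contrast is at least 5 SD above the additive Gaussian noise.
#'
#' @param cfg A [scenario_config()] with a non-NULL `grid_dim`.
#' @param positions A [particle_table()] from [generate_particle_positions()].
#' @param truth Matching ground truth (provides the per-particle masses).
#' @param voxel_size Voxel size in Angstrom (defaults to `cfg$voxel_size`).
#' @return A [voxel_volume()]; ground-truth foreground amplitude is attached
#'   as attribute `foreground_amplitude`.
#' @export
generate_tomogram_volume <- function(cfg, positions, truth,
                                     voxel_size = cfg$voxel_size) {
  stopifnot(inherits(cfg, "scenario_config"))
  if (is.null(cfg$grid_dim))
    ng_error("cfg$grid_dim must be set to render a volume",
             "ng_invalid_argument")
  d <- as.integer(cfg$grid_dim)
  tp <- truth$particles
  per_vox <- voxels_to_mass(1L, voxel_size)
  amp <- if (cfg$noise_sd > 0) 5 * cfg$noise_sd else 1
  with_rng_seed(cfg$seed + 1L, {
    signal <- array(0, dim = d)
    for (i in seq_len(nrow(tp))) {
      nv <- max(1L, round(tp$mass[i] / per_vox))
      k <- (3 * nv / (4 * pi))^(1 / 3)
      rr <- as.integer(ceiling(k + 1.5))
      p <- c(tp$x[i], tp$y[i], tp$z[i])
      off <- expand.grid(ox = -rr:rr, oy = -rr:rr, oz = -rr:rr)
      vx <- round(p[1]) + off$ox
      vy <- round(p[2]) + off$oy
      vz <- round(p[3]) + off$oz
      d2 <- (vx - p[1])^2 + (vy - p[2])^2 + (vz - p[3])^2
      sel <- order(d2)[seq_len(nv)]
      vx <- vx[sel]; vy <- vy[sel]; vz <- vz[sel]
      if (any(vx < 0 | vx >= d[1] | vy < 0 | vy >= d[2] |
              vz < 0 | vz >= d[3]))
        ng_error(sprintf("particle %d overlaps the grid boundary", i),
                 "ng_out_of_bounds")
      signal[cbind(vx + 1L, vy + 1L, vz + 1L)] <- amp
    }
    data <- signal
    if (cfg$noise_sd > 0)
      data <- data + array(stats::rnorm(prod(d), 0, cfg$noise_sd), dim = d)
    vol <- voxel_volume(data, voxel_size = voxel_size)
    attr(vol, "foreground_amplitude") <- amp
    vol
  })
}

#' Generate a class-structured subvolume set
#'
#' Builds `n_classes` distinct structured templates (each a fixed random
#' arrangement of Gaussian blobs, standardized to unit variance) and
#' instantiates each `n_per_class` times with additive Gaussian noise at the
#' requested SNR (signal variance / noise variance). Emulates the inputs of
#' classification-reproducibility experiments.
#'
#' @param n_classes Number of distinct classes (>= 1).
#' @param n_per_class Copies per class.
#' @param box Cubic box edge in voxels (>= 8).
#' @param snr Signal-to-noise ratio; `Inf` means noise-free.
#' @param seed Integer seed.
#' @param voxel_size Voxel size stamped on the subvolumes (Angstrom).
#' @return A list with `subvolumes` (list of [voxel_volume()]),
#'   `truth` (data.frame with `index`, `class_label`) and `templates`
#'   (the noise-free class templates).
#' @export
generate_subvolume_set <- function(n_classes, n_per_class, box, snr,
                                   seed = 1L, voxel_size = 13.68) {
  ng_stopifnot(n_classes >= 1, "n_classes must be >= 1")
  ng_stopifnot(box >= 8, "box must be >= 8 voxels")
  with_rng_seed(seed, {
    g <- grid_coords(c(box, box, box))
    templates <- lapply(seq_len(n_classes), function(k) {
      sig <- numeric(ncol(g))
      for (b in 1:4) {
        ctr <- stats::runif(3, box * 0.25, box * 0.75)
        s <- stats::runif(1, box / 12, box / 7)
        sig <- sig + exp(-colSums((g - ctr)^2) / (2 * s^2))
      }
      sig <- (sig - mean(sig)) / stats::sd(sig)
      array(sig, dim = c(box, box, box))
    })
    noise_sd <- if (is.infinite(snr)) 0 else sqrt(1 / snr)
    subvols <- vector("list", n_classes * n_per_class)
    labels <- integer(length(subvols))
    i <- 0L
    for (k in seq_len(n_classes)) {
      for (j in seq_len(n_per_class)) {
        i <- i + 1L
        dat <- templates[[k]]
        if (noise_sd > 0)
          dat <- dat + array(stats::rnorm(box^3, 0, noise_sd),
                             dim = dim(dat))
        subvols[[i]] <- voxel_volume(dat, voxel_size = voxel_size)
        labels[i] <- k
      }
    }
    list(subvolumes = subvols,
         truth = data.frame(index = seq_along(labels), class_label = labels),
         templates = lapply(templates, voxel_volume,
                            voxel_size = voxel_size))
  })
}
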