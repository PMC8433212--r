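# FNV-1a 32-bit hash of a string, in exact double arithmetic (products are
# split 16/16 bits to stay below 2^53)
fnv1a32 <- function(s) {
  h <- 2166136261
  p <- 16777619
  for (b in utf8ToInt(enc2utf8(s))) {
    h <- bitwXor(as.integer(h %% 65536), as.integer(b %% 256)) +
      floor(h / 65536) * 65536
    lo <- h %% 65536
    hi <- floor(h / 65536)
    h <- ((lo * p) + ((hi * p) %% 65536) * 65536) %% 4294967296
  }
  h
}

hash_token <- function(s) {
  h <- fnv1a32(s)
  sprintf("S%04x%04x", floor(h / 65536), h %% 65536)
}

#' Blind experimental conditions
#'
#' Replaces the condition column by salted hash tokens so downstream
#' analysis cannot be influenced by knowledge of the experimental state;
#' the returned map inverts the blinding.
#'
#' @param table A [particle_table()] with conditions present.
#' @param salt Salt string mixed into the hash.
#' @return A list with `table` (blinded) and `map` (a `blinding_map`:
#'   data.frame of condition/token pairs plus the salt).
#' @export
blind_conditions <- function(table, salt) {
  if (all(is.na(table$condition)))
    ng_error("no conditions to blind", "ng_invalid_argument")
  conds <- sort(unique(stats::na.omit(table$condition)))
  tokens <- vapply(conds, function(cc) hash_token(paste0(salt, ":", cc)), "")
  map <- structure(data.frame(condition = conds, token = unname(tokens),
                              stringsAsFactors = FALSE),
                   salt = salt, class = c("blinding_map", "data.frame"))
  table$condition <- unname(tokens[match(table$condition, conds)])
  list(table = table, map = map)
}

#' Reverse condition blinding
#' @param table A blinded [particle_table()].
#' @param map The `blinding_map` returned by [blind_conditions()].
#' @return The table with original condition labels.
#' @export
unblind_conditions <- function(table, map) {
  idx <- match(table$condition, map$token)
  table$condition <- map$condition[idx]
  table
}

#' Default pipeline configuration
#'
#' A runnable demo configuration: simulate one synthetic nucleolar
#' tomogram (three shell classes), fit the nucleolar sphere, and run the
#' radial statistics. All stage parameters mirror the package defaults
#' (sigma 3 voxels, target mass 4.5 MDa, protein density 1.3 g/cm^3,
#' top-N 600/400, consensus distance 4 voxels, quorum 5 of 6, 10 classes,
#' 10 annealing + 30 hill-climbing iterations, < 1% convergence).
#'
#' @param seed Master seed.
#' @return A named list of class `pipeline_config`.
#' @export
default_pipeline_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    stages = list(simulate = TRUE, fit_spheres = TRUE, stats = TRUE),
    scenario = list(sphere_center = c(160, 160, 160), sphere_radius = 120,
                    classes = list(
                      list(label = 1, count = 200, shell_mean = 0.85,
                           shell_sd = 0.05),
                      list(label = 2, count = 200, shell_mean = 0.95,
                           shell_sd = 0.05),
                      list(label = 3, count = 200, shell_mean = 1.00,
                           shell_sd = 0.05)),
                    background_spectrum = NULL, surface_spike = NULL,
                    voxel_size = 13.68),
    inputs = list(particles = NULL),
    fit = list(max_iter = 50, min_inliers = 10),
    stats = list(n_perm = 2000, bandwidth = "auto"),
    blinding = list(salt = NULL)
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Unspecified fields fall back to [default_pipeline_config()].
#'
#' @param path Path to a YAML or JSON config file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path))
    ng_error(sprintf("config file not found: %s", path), "ng_config_error")
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
         else yaml::read_yaml(path)
  cfg <- default_pipeline_config()
  merge_in <- function(base, upd) {
    for (nm in names(upd)) {
      if (is.list(upd[[nm]]) && is.list(base[[nm]]) &&
          !is.null(names(upd[[nm]])))
        base[[nm]] <- merge_in(base[[nm]], upd[[nm]])
      else
        base[nm] <- list(upd[[nm]])   # preserves explicit NULLs ("~")
    }
    base
  }
  structure(merge_in(unclass(cfg), raw), class = "pipeline_config")
}

validate_pipeline_config <- function(cfg) {
  st <- cfg$stages
  if (isTRUE(st$fit_spheres) && !isTRUE(st$simulate) &&
      is.null(cfg$inputs$particles))
    ng_error("config field 'inputs.particles' is required when stage 'fit_spheres' runs without 'simulate'",
             "ng_config_error")
  if (isTRUE(st$stats) && !isTRUE(st$fit_spheres))
    ng_error("config field 'stages.fit_spheres' must be enabled for stage 'stats'",
             "ng_config_error")
  invisible(cfg)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the analysis pipeline
#'
#' Executes the enabled stages in dependency order (simulate ->
#' fit-spheres -> stats), writing every artifact plus a manifest (inputs,
#' parameters, seed, package version) to `out_dir`. Re-running with the
#' same configuration reproduces identical outputs. A stage failure writes
#' a machine-readable `error.json` and halts; earlier outputs are kept.
#'
#' @param cfg A `pipeline_config` (see [default_pipeline_config()],
#'   [read_pipeline_config()]).
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly; artifacts are files inside it.
#' @export
run_pipeline <- function(cfg, out_dir) {
  validate_pipeline_config(cfg)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  artifacts <- character()
  stage <- "setup"
  result <- tryCatch({
    particles <- NULL
    if (isTRUE(cfg$stages$simulate)) {
      stage <- "simulate"
      sc_args <- cfg$scenario
      sc_args$seed <- cfg$seed
      sc <- do.call(scenario_config, sc_args)
      gen <- generate_particle_positions(sc)
      particles <- gen$particles
      artifacts["particles"] <- write_tsv(as.data.frame(particles),
                                          file.path(out_dir, "particles.tsv"))
      artifacts["truth"] <- write_tsv(gen$truth$particles,
                                      file.path(out_dir, "truth.tsv"))
    } else if (!is.null(cfg$inputs$particles)) {
      stage <- "load"
      particles <- read_particle_table(cfg$inputs$particles)
    }
    blind_map <- NULL
    if (!is.null(cfg$blinding$salt) && !all(is.na(particles$condition))) {
      stage <- "blind"
      bl <- blind_conditions(particles, cfg$blinding$salt)
      particles <- bl$table
      blind_map <- bl$map
      artifacts["blinding_map"] <- write_tsv(as.data.frame(bl$map),
                                             file.path(out_dir,
                                                       "blinding_map.tsv"))
    }
    fits <- NULL
    if (isTRUE(cfg$stages$fit_spheres)) {
      stage <- "fit_spheres"
      fits <- fit_spheres_per_tomogram(particles,
                                       max_iter = cfg$fit$max_iter,
                                       min_inliers = cfg$fit$min_inliers)
      artifacts["sphere_fits"] <- write_tsv(
        sphere_fit_table(fits, voxel_size = cfg$scenario$voxel_size),
        file.path(out_dir, "sphere_fits.tsv"))
    }
    if (isTRUE(cfg$stages$stats)) {
      stage <- "stats"
      tab <- normalized_distances(particles, fits)
      classes <- sort(unique(stats::na.omit(tab$class_label)))
      pdf_rows <- list(); test_rows <- list()
      for (k in classes) {
        dk <- tab$normalized_distance[tab$class_label %in% k]
        pdf <- radial_pdf(dk, bandwidth = cfg$stats$bandwidth)
        pdf_rows[[as.character(k)]] <-
          data.frame(class_label = k, grid = pdf$grid,
                     density = pdf$density)
      }
      if (length(classes) >= 2) {
        pairs <- utils::combn(classes, 2)
        for (j in seq_len(ncol(pairs))) {
          a <- pairs[1, j]; b <- pairs[2, j]
          tt <- permutation_test(
            tab$normalized_distance[tab$class_label %in% a],
            tab$normalized_distance[tab$class_label %in% b],
            statistic = "mean_diff", alternative = "two_sided",
            n_perm = cfg$stats$n_perm, seed = cfg$seed)
          test_rows[[j]] <- data.frame(class_a = a, class_b = b,
                                       statistic = tt$statistic_name,
                                       observed = tt$observed,
                                       p_value = tt$p_value,
                                       stars = significance_stars(tt$p_value))
        }
      }
      artifacts["radial_pdfs"] <- write_tsv(do.call(rbind, pdf_rows),
                                            file.path(out_dir,
                                                      "radial_pdfs.tsv"))
      if (length(test_rows))
        artifacts["tests"] <- write_tsv(do.call(rbind, test_rows),
                                        file.path(out_dir,
                                                  "permutation_tests.tsv"))
    }
    manifest <- list(
      package = "nucleogradient",
      version = as.character(utils::packageVersion("nucleogradient")),
      seed = cfg$seed,
      config = unclass(cfg),
      artifacts = as.list(basename(artifacts)))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, null = "null")
    invisible(out_dir)
  }, ng_error = function(e) {
    report <- list(stage = stage, error = conditionMessage(e),
                   class = class(e)[1])
    jsonlite::write_json(report, file.path(out_dir, "error.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    ng_error(sprintf("pipeline stage '%s' failed: %s", stage,
                     conditionMessage(e)), "ng_stage_error")
  })
  result
}

#' Digest the artifacts of a pipeline run
#'
#' MD5 digests of every regular file in a run directory, for
#' reproducibility checks (two runs with identical configuration produce
#' identical digests).
#'
#' @param out_dir A pipeline output directory.
#' @return Named character vector of digests keyed by file name.
#' @export
pipeline_digests <- function(out_dir) {
  files <- sort(list.files(out_dir, full.names = TRUE))
  files <- files[!dir.exists(files)]
  dg <- tools::md5sum(files)
  names(dg) <- basename(files)
  dg
}
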