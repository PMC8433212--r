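#' Construct a particle table
#'
#' The universal point type of the package: one row per particle with its
#' position (0-based voxel coordinates), an optional matching score in
#' \[-1, 1\], an optional non-negative integer class label, the tomogram the
#' particle came from, and an optional experimental condition (e.g. log,
#' stationary, DAZ, dark, or a blinded token).
#'
#' @param tomogram_id Character vector, non-empty per record.
#' @param x,y,z Numeric positions in voxels (0-based).
#' @param score Numeric or NA.
#' @param class_label Integer (>= 0) or NA.
#' @param condition Character or NA.
#' @param provenance Free-text metadata attached as an attribute.
#' @return A `data.frame` of class `particle_table`.
#' @export
particle_table <- function(tomogram_id, x, y, z, score = NA_real_,
                           class_label = NA_integer_,
                           condition = NA_character_, provenance = "") {
  tomogram_id <- as.character(tomogram_id)
  if (length(tomogram_id) && any(is.na(tomogram_id) | !nzchar(tomogram_id)))
    ng_error("tomogram_id must be non-empty for every record",
             "ng_invalid_argument")
  if (!all(is.finite(c(x, y, z))))
    ng_error("particle positions must be finite", "ng_invalid_argument")
  cl <- suppressWarnings(as.integer(class_label))
  if (any(!is.na(cl) & cl < 0))
    ng_error("class_label must be a non-negative integer when present",
             "ng_invalid_argument")
  df <- data.frame(tomogram_id = tomogram_id,
                   x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
                   score = as.numeric(rep_len(score, length(tomogram_id))),
                   class_label = rep_len(cl, length(tomogram_id)),
                   condition = as.character(rep_len(condition,
                                                    length(tomogram_id))),
                   stringsAsFactors = FALSE)
  attr(df, "provenance") <- provenance
  class(df) <- c("particle_table", "data.frame")
  df
}

as_particle_table <- function(df, provenance = "") {
  particle_table(df$tomogram_id, df$x, df$y, df$z,
                 score = if (is.null(df$score)) NA_real_ else df$score,
                 class_label = if (is.null(df$class_label)) NA_integer_
                               else df$class_label,
                 condition = if (is.null(df$condition)) NA_character_
                             else df$condition,
                 provenance = provenance)
}

# STAR tag <-> column mapping (RELION-style tags for interoperability with
# motive lists exported from matching tools)
.star_tags <- c(tomogram_id = "_rlnMicrographName",
                x = "_rlnCoordinateX",
                y = "_rlnCoordinateY",
                z = "_rlnCoordinateZ",
                score = "_rlnAutopickFigureOfMerit",
                class_label = "_rlnClassNumber",
                condition = "_ngCondition")

#' Write a particle table
#'
#' @param table A [particle_table()].
#' @param path Output path.
#' @param format `"tsv"` (tab-separated with header) or `"star"`
#'   (STAR-style loop).
#' @return `path`, invisibly.
#' @export
write_particle_table <- function(table, path, format = c("tsv", "star")) {
  format <- match.arg(format)
  cols <- c("tomogram_id", "x", "y", "z", "score", "class_label", "condition")
  df <- as.data.frame(table)[, cols]
  if (format == "tsv") {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    lines <- c("data_particles", "", "loop_",
               sprintf("%s #%d", .star_tags[cols], seq_along(cols)))
    body <- do.call(paste, c(lapply(df, function(v) {
      out <- as.character(v)
      out[is.na(v)] <- "NA"
      out
    }), sep = "\t"))
    writeLines(c(lines, body), path)
  }
  invisible(path)
}

#' Read a particle table
#'
#' Accepts either the package's tab-separated format (header columns
#' tomogram_id, x, y, z, score, class_label, condition) or a STAR-style loop
#' with the corresponding tags; the format is auto-detected.
#'
#' @param path Path to a table file.
#' @return A [particle_table()].
#' @export
read_particle_table <- function(path) {
  if (!file.exists(path))
    ng_error(sprintf("particle table not found: %s", path), "ng_missing_file")
  first <- readLines(path, n = 20L, warn = FALSE)
  if (any(grepl("^\\s*loop_\\s*$", first)) || grepl("^data_", first[1]))
    read_star_particles(path)
  else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    as_particle_table(df, provenance = path)
  }
}

read_star_particles <- function(path) {
  lines <- readLines(path, warn = FALSE)
  loop_at <- which(grepl("^\\s*loop_\\s*$", lines))
  if (!length(loop_at))
    ng_error(sprintf("no loop_ block in STAR file %s", path),
             "ng_malformed_table")
  i <- loop_at[1] + 1L
  tags <- character()
  while (i <= length(lines) && grepl("^\\s*_", lines[i])) {
    tags <- c(tags, sub("^\\s*(_\\S+).*$", "\\1", lines[i]))
    i <- i + 1L
  }
  body <- lines[seq(i, length(lines))]
  body <- body[nzchar(trimws(body)) & !grepl("^data_", body)]
  fields <- strsplit(trimws(body), "\\s+")
  if (any(lengths(fields) != length(tags)))
    ng_error(sprintf("ragged STAR rows in %s", path), "ng_malformed_table")
  m <- do.call(rbind, fields)
  col_of <- function(key) {
    j <- match(.star_tags[[key]], tags)
    if (is.na(j)) NULL else m[, j]
  }
  need <- c("tomogram_id", "x", "y", "z")
  for (key in need)
    if (is.null(col_of(key)))
      ng_error(sprintf("STAR file %s lacks tag %s", path, .star_tags[[key]]),
               "ng_malformed_table")
  num <- function(v) if (is.null(v)) NA_real_ else suppressWarnings(as.numeric(v))
  particle_table(col_of("tomogram_id"),
                 num(col_of("x")), num(col_of("y")), num(col_of("z")),
                 score = num(col_of("score")),
                 class_label = num(col_of("class_label")),
                 condition = if (is.null(col_of("condition"))) NA_character_
                             else ifelse(col_of("condition") == "NA",
                                         NA_character_, col_of("condition")),
                 provenance = path)
}
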