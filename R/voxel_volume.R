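#' Construct a voxel volume
#'
#' The universal raster type of the package: a 3D density grid with an
#' isotropic physical voxel size in Angstrom. Used for tomograms, templates,
#' class averages and subvolumes alike.
#'
#' Coordinates are 0-based: the center of the first voxel is (0,0,0) and the
#' grid is addressed (x, y, z) with x fastest, matching MRC storage order.
#' The `origin` field is carried through I/O but ignored for geometry; all
#' positions in the package live in the volume's own voxel frame.
#'
#' @param data Numeric 3D array (x, y, z).
#' @param voxel_size Voxel edge length in Angstrom (single positive number).
#' @param origin Numeric length-3 vector, in voxels. Metadata only.
#' @return An object of class `voxel_volume`.
#' @export
voxel_volume <- function(data, voxel_size, origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    ng_error("`data` must be a 3D array", "ng_invalid_argument")
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L ||
      !is.finite(voxel_size) || voxel_size <= 0)
    ng_error("`voxel_size` must be a single positive number",
             "ng_invalid_argument")
  if (!all(is.finite(data)))
    ng_error("volume contains non-finite values", "ng_invalid_argument")
  storage.mode(data) <- "double"
  structure(list(data = data, voxel_size = as.numeric(voxel_size),
                 origin = as.numeric(origin)),
            class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<voxel_volume> %d x %d x %d voxels @ %.4g A/voxel\n",
              d[1], d[2], d[3], x$voxel_size))
  cat(sprintf("  range [%.4g, %.4g], mean %.4g\n",
              min(x$data), max(x$data), mean(x$data)))
  invisible(x)
}

#' @export
dim.voxel_volume <- function(x) dim(x$data)

is_voxel_volume <- function(x) inherits(x, "voxel_volume")

assert_volume <- function(vol) {
  if (!is_voxel_volume(vol))
    ng_error("expected a voxel_volume", "ng_invalid_argument")
  invisible(vol)
}
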