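#' Read a density volume from an MRC file
#'
#' Reads MRC2014 volumes (modes 0, 1, 2 and 6; i.e. int8, int16, float32,
#' uint16). Data are promoted to double precision. The voxel size is taken
#' from the header cell dimensions divided by the grid sampling; the header
#' origin (Angstrom) is converted to voxels and carried as metadata only.
#'
#' @param path Path to an MRC file.
#' @return A [voxel_volume()].
#' @seealso [save_volume()]
#' @export
load_volume <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    ng_error(sprintf("MRC file not found: %s", path), "ng_missing_file")
  fsize <- file.info(path)$size
  if (is.na(fsize) || fsize < 1024)
    ng_error(sprintf("file too small to hold an MRC header: %s", path),
             "ng_malformed_header")
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_int <- readBin(con, "integer", n = 256, size = 4, endian = "little")
  seek(con, 0)
  hdr_dbl <- readBin(con, "double", n = 256, size = 4, endian = "little")
  nx <- hdr_int[1]; ny <- hdr_int[2]; nz <- hdr_int[3]
  mode <- hdr_int[4]
  mx <- hdr_int[8]; my <- hdr_int[9]; mz <- hdr_int[10]
  cella <- hdr_dbl[11:13]
  nsymbt <- hdr_int[24]
  if (any(is.na(c(nx, ny, nz, mode))) || nx < 1 || ny < 1 || nz < 1 ||
      nx > 1e5 || ny > 1e5 || nz > 1e5 || is.na(nsymbt) || nsymbt < 0)
    ng_error(sprintf("malformed MRC header in %s", path),
             "ng_malformed_header")
  bytes_per <- switch(as.character(mode),
                      "0" = 1L, "1" = 2L, "2" = 4L, "6" = 2L, NA_integer_)
  if (is.na(bytes_per))
    ng_error(sprintf("unsupported MRC mode %d in %s (modes 0/1/2/6 supported)",
                     mode, path), "ng_unsupported_mode")
  n_vox <- as.numeric(nx) * ny * nz
  if (1024 + nsymbt + n_vox * bytes_per > fsize)
    ng_error(sprintf("MRC data truncated in %s", path), "ng_malformed_header")
  seek(con, 1024 + nsymbt)
  data <- switch(as.character(mode),
    "0" = readBin(con, "integer", n = n_vox, size = 1, signed = TRUE,
                  endian = "little"),
    "1" = readBin(con, "integer", n = n_vox, size = 2, signed = TRUE,
                  endian = "little"),
    "2" = readBin(con, "double", n = n_vox, size = 4, endian = "little"),
    "6" = readBin(con, "integer", n = n_vox, size = 2, signed = FALSE,
                  endian = "little"))
  arr <- array(as.double(data), dim = c(nx, ny, nz))
  # sampling defaults to the grid when MX/MY/MZ are unset
  mx <- if (is.na(mx) || mx <= 0) nx else mx
  vsize <- if (is.finite(cella[1]) && cella[1] > 0) cella[1] / mx else 1
  origin_ang <- hdr_dbl[50:52]
  origin <- if (all(is.finite(origin_ang))) origin_ang / vsize else c(0, 0, 0)
  voxel_volume(arr, voxel_size = vsize, origin = origin)
}

#' Write a density volume to an MRC file
#'
#' Writes MRC2014 mode 2 (32-bit float). `load_volume(save_volume(v))` is
#' the identity up to float32 rounding of the data and voxel size.
#'
#' @param vol A [voxel_volume()].
#' @param path Output path; the parent directory must exist.
#' @return `path`, invisibly.
#' @export
save_volume <- function(vol, path) {
  assert_volume(vol)
  if (!dir.exists(dirname(path)))
    ng_error(sprintf("cannot write %s: directory does not exist", path),
             "ng_unwritable_path")
  d <- dim(vol$data)
  con <- tryCatch(file(path, "wb"),
                  error = function(e) ng_error(
                    sprintf("cannot open %s for writing", path),
                    "ng_unwritable_path"))
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.double(x), con, size = 4, endian = "little")
  wi(d)                                   # NX NY NZ
  wi(2L)                                  # MODE 2 = float32
  wi(c(0L, 0L, 0L))                       # N*START
  wi(d)                                   # MX MY MZ
  wf(d * vol$voxel_size)                  # CELLA (Angstrom)
  wf(c(90, 90, 90))                       # CELLB
  wi(c(1L, 2L, 3L))                       # MAPC MAPR MAPS
  wf(c(min(vol$data), max(vol$data), mean(vol$data)))  # DMIN DMAX DMEAN
  wi(1L)                                  # ISPG: volume
  wi(0L)                                  # NSYMBT
  wi(rep(0L, 2))                          # EXTRA words 25-26
  writeChar("    ", con, nchars = 4, eos = NULL)       # EXTTYP (unused)
  wi(20140L)                              # NVERSION
  wi(rep(0L, 21))                         # EXTRA words 29-49
  wf(vol$origin * vol$voxel_size)         # ORIGIN (Angstrom)
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)     # MACHST little-endian
  wf(stats::sd(vol$data))                 # RMS
  wi(0L)                                  # NLABL
  writeBin(raw(800), con)                 # labels
  wf(vol$data)
  invisible(path)
}
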