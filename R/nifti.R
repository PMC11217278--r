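# Minimal NIfTI-1 I/O.
#
# No NIfTI package ships with this environment's R stack, so the package
# carries its own single-file reader/writer covering the subset the pipeline
# emits: 3-D volumes, little/big-endian detection on read, dtypes uint8 /
# int16 / int32 / float32 / float64, sform affine (qform ignored; falls back
# to a pixdim-diagonal affine when sform_code == 0). Writes .nii or .nii.gz
# (by extension), always little-endian float32 unless the data are integral.

NIFTI_DTYPES <- list(
  `2`  = list(what = "integer", size = 1L, signed = FALSE),
  `4`  = list(what = "integer", size = 2L, signed = TRUE),
  `8`  = list(what = "integer", size = 4L, signed = TRUE),
  `16` = list(what = "double",  size = 4L, signed = TRUE),
  `64` = list(what = "double",  size = 8L, signed = TRUE)
)

nii_connection <- function(path, open) {
  if (grepl("\\.gz$", path)) gzfile(path, open) else file(path, open)
}

#' Read a NIfTI-1 volume
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param kind tag stored on the returned [scalar_volume()].
#' @return a `scalar_volume`.
#' @export
read_nifti <- function(path, kind = "scalar") {
  if (!file.exists(path)) abort_data(sprintf("read_nifti: no such file: %s", path))
  con <- nii_connection(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 348)
  if (length(hdr) < 348) abort_data(sprintf("read_nifti: truncated header in %s", path))
  endian <- "little"
  sizeof_hdr <- readBin(hdr[1:4], "integer", 1, 4, endian = endian)
  if (sizeof_hdr != 348L) {
    endian <- "big"
    sizeof_hdr <- readBin(hdr[1:4], "integer", 1, 4, endian = endian)
    if (sizeof_hdr != 348L) abort_data(sprintf("read_nifti: %s is not NIfTI-1 (bad sizeof_hdr)", path))
  }
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1")) abort_data(sprintf("read_nifti: bad magic '%s' in %s", magic, path))
  int2 <- function(off, n = 1) readBin(hdr[(off + 1):(off + 2 * n)], "integer", n, 2, endian = endian)
  int4 <- function(off, n = 1) readBin(hdr[(off + 1):(off + 4 * n)], "integer", n, 4, endian = endian)
  flt4 <- function(off, n = 1) readBin(hdr[(off + 1):(off + 4 * n)], "double", n, 4, endian = endian)
  dims <- int2(40, 8)
  ndim <- dims[1]
  if (ndim < 3) abort_data("read_nifti: need at least 3 dimensions")
  d <- dims[2:4]
  nvox_extra <- if (ndim > 3) prod(pmax(dims[5:(1 + ndim)], 1L)) else 1L
  if (nvox_extra != 1L) abort_data("read_nifti: only 3-D volumes supported")
  datatype <- int2(70)
  dt <- NIFTI_DTYPES[[as.character(datatype)]]
  if (is.null(dt)) abort_data(sprintf("read_nifti: unsupported datatype code %d", datatype))
  pixdim <- flt4(76, 8)
  vox_offset <- flt4(108)
  scl_slope <- flt4(112); scl_inter <- flt4(116)
  sform_code <- int2(254)
  srow <- matrix(flt4(280, 12), 3, 4, byrow = TRUE)
  affine <- diag(4)
  if (sform_code > 0) {
    affine[1:3, ] <- srow
  } else {
    affine[1, 1] <- pixdim[2]; affine[2, 2] <- pixdim[3]; affine[3, 3] <- pixdim[4]
  }
  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", skip)
  n <- prod(d)
  vals <- readBin(con, dt$what, n, dt$size, signed = dt$signed, endian = endian)
  if (length(vals) < n) abort_data(sprintf("read_nifti: truncated data in %s", path))
  vals <- as.double(vals)
  if (scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  scalar_volume(array(vals, d), affine, kind)
}

#' Write a NIfTI-1 volume
#'
#' Integer-valued data (label volumes) are stored as int32, everything else as
#' float32. Gzip compression is chosen by the `.gz` extension.
#'
#' @param vol a [scalar_volume()].
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(vol, path) {
  d <- dim(vol$data)
  vals <- as.vector(vol$data)
  integral <- all(vals == round(vals)) && max(abs(vals)) < 2^31 - 1
  datatype <- if (integral) 8L else 16L
  bitpix <- if (integral) 32L else 32L
  vox <- voxel_size(vol)
  hdr <- raw(348)
  put_int4 <- function(off, v) hdr[(off + 1):(off + 4 * length(v))] <<- writeBin(as.integer(v), raw(), 4, endian = "little")
  put_int2 <- function(off, v) hdr[(off + 1):(off + 2 * length(v))] <<- writeBin(as.integer(v), raw(), 2, endian = "little")
  put_flt4 <- function(off, v) hdr[(off + 1):(off + 4 * length(v))] <<- writeBin(as.double(v), raw(), 4, endian = "little")
  put_int4(0, 348L)
  put_int2(40, c(3L, d, 1L, 1L, 1L, 1L))
  put_int2(70, datatype)
  put_int2(72, bitpix)
  put_flt4(76, c(1, vox, 1, 1, 1, 1))
  put_flt4(108, 352)          # vox_offset
  put_flt4(112, 1); put_flt4(116, 0)  # scl_slope/inter
  put_int2(252, 0L)           # qform_code
  put_int2(254, 2L)           # sform_code: aligned
  put_flt4(280, t(vol$affine[1:3, ]))
  hdr[345:348] <- c(charToRaw("n+1"), as.raw(0))
  con <- nii_connection(path, "wb")
  on.exit(close(con))
  writeBin(hdr, con)
  writeBin(raw(4), con)  # extension flag
  if (integral) writeBin(as.integer(vals), con, 4, endian = "little")
  else          writeBin(as.double(vals), con, 4, endian = "little")
  invisible(path)
}
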