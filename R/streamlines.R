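#' Streamline set
#'
#' A packed container for ordered polylines in world mm, in the style of
#' tractography toolkits: one tall coordinate matrix plus per-streamline
#' offsets. Each streamline may carry the index of the mesh vertex it was
#' seeded from and, after classification, its terminal cortical label.
#'
#' @param coords N x 3 matrix of point coordinates (world mm), streamlines
#'   concatenated.
#' @param lengths integer vector of points per streamline (each >= 2).
#' @param seed_vertex optional integer vector (1-based mesh vertex per
#'   streamline).
#' @param terminal_label optional integer vector of terminal cortical labels.
#' @return an object of class `streamline_set`.
#' @export
streamline_set <- function(coords, lengths, seed_vertex = NULL, terminal_label = NULL) {
  coords <- rbind_pts(coords)
  lengths <- as.integer(lengths)
  if (length(lengths) && any(lengths < 2L)) abort_data("streamline_set: every streamline needs >= 2 points")
  if (sum(lengths) != nrow(coords)) abort_data("streamline_set: lengths do not sum to nrow(coords)")
  if (!is.null(seed_vertex) && length(seed_vertex) != length(lengths))
    abort_data("streamline_set: seed_vertex length mismatch")
  if (!is.null(terminal_label) && length(terminal_label) != length(lengths))
    abort_data("streamline_set: terminal_label length mismatch")
  structure(list(coords = coords, lengths = lengths,
                 offsets = c(0L, cumsum(lengths)),
                 seed_vertex = if (is.null(seed_vertex)) NULL else as.integer(seed_vertex),
                 terminal_label = if (is.null(terminal_label)) NULL else as.integer(terminal_label)),
            class = "streamline_set")
}

#' @export
print.streamline_set <- function(x, ...) {
  cat(sprintf("<streamline_set> %d streamlines, %d points%s\n",
              n_streamlines(x), nrow(x$coords),
              if (!is.null(x$seed_vertex)) ", seeded" else ""))
  invisible(x)
}

#' @rdname streamline_set
#' @param x a `streamline_set`.
#' @export
n_streamlines <- function(x) length(x$lengths)

#' @rdname streamline_set
#' @param i streamline index.
#' @export
streamline_points <- function(x, i) {
  x$coords[(x$offsets[i] + 1):x$offsets[i + 1], , drop = FALSE]
}

# final point of every streamline, n x 3
streamline_endpoints <- function(x) {
  x$coords[x$offsets[-1], , drop = FALSE]
}

from_polylines <- function(lst, seed_vertex = NULL, terminal_label = NULL) {
  streamline_set(do.call(rbind, lst), vapply(lst, nrow, 0L), seed_vertex, terminal_label)
}

#' Read and write MRtrix TCK track files
#'
#' Binary Float32LE track format: a text header terminated by `END`, then
#' xyz triplets with a NaN-triplet separator per streamline and an
#' Inf-triplet end-of-file marker. Coordinates are world mm.
#'
#' @param streams a [streamline_set()].
#' @param path file path (`.tck`).
#' @return `path` / a `streamline_set`.
#' @export
write_tck <- function(streams, path) {
  hdr_lines <- c("mrtrix tracks", "datatype: Float32LE",
                 sprintf("count: %d", n_streamlines(streams)))
  # offset must include its own line; fixed-width field sidesteps the
  # chicken-and-egg problem
  probe <- paste0(paste(hdr_lines, collapse = "\n"), "\nfile: . OFFSETPL\nEND\n")
  offset <- nchar(probe)
  hdr <- sub("OFFSETPL", formatC(offset, width = 8, flag = "0"), probe)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(hdr), con)
  n <- n_streamlines(streams)
  total <- nrow(streams$coords) + n + 1L
  buf <- matrix(NA_real_, 3, total)
  at <- 1L
  for (i in seq_len(n)) {
    pts <- streamline_points(streams, i)
    buf[, at:(at + nrow(pts) - 1L)] <- t(pts)
    at <- at + nrow(pts) + 1L  # leave the NaN separator column
  }
  buf[, total] <- Inf
  writeBin(as.vector(buf), con, size = 4, endian = "little")
  invisible(path)
}

#' @rdname write_tck
#' @export
read_tck <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  first <- readBin(con, "raw", 13)
  if (!identical(rawToChar(first), "mrtrix tracks"))
    abort_data(sprintf("read_tck: %s is not a TCK file", path))
  # read header bytes until END
  hdr <- rawToChar(first)
  repeat {
    b <- readBin(con, "raw", 1)
    if (!length(b)) abort_data("read_tck: header missing END")
    hdr <- paste0(hdr, rawToChar(b))
    if (grepl("\nEND\n$", hdr)) break
    if (nchar(hdr) > 65536) abort_data("read_tck: runaway header")
  }
  lines <- strsplit(hdr, "\n")[[1]]
  fl <- grep("^file: ", lines, value = TRUE)
  if (!length(fl)) abort_data("read_tck: header lacks file offset")
  offset <- as.integer(sub("^file: \\S+ ", "", fl[1]))
  dt <- sub("^datatype: ", "", grep("^datatype: ", lines, value = TRUE)[1])
  if (!identical(dt, "Float32LE")) abort_data(sprintf("read_tck: unsupported datatype %s", dt))
  seek(con, offset)
  vals <- readBin(con, "double", n = file.size(path), size = 4, endian = "little")
  m <- matrix(vals, nrow = 3)
  isnan <- apply(is.nan(m), 2, any)
  isinf <- apply(is.infinite(m), 2, any)
  end <- which(isinf)[1]
  if (is.na(end)) abort_data("read_tck: missing end-of-file triplet")
  m <- m[, seq_len(end - 1), drop = FALSE]
  sep <- isnan[seq_len(end - 1)]
  grp <- cumsum(c(TRUE, head(sep, -1))) # streamline id per column
  keep <- !sep
  lengths <- as.integer(table(factor(grp[keep], levels = unique(grp[keep]))))
  streamline_set(t(m[, keep, drop = FALSE]), lengths)
}

#' Read and write TrackVis TRK files
#'
#' TRK v2 stores points in "voxel-mm" coordinates tied to a reference volume;
#' the reader/writer converts to and from world mm using the header's
#' vox_to_ras matrix (written from `ref_affine`), following the half-voxel
#' origin convention.
#'
#' @param streams a [streamline_set()].
#' @param path file path (`.trk`).
#' @param ref_affine 4x4 voxel-to-world affine of the reference grid.
#' @param ref_dim integer grid dimensions (length 3).
#' @return `path` / a `streamline_set`.
#' @export
write_trk <- function(streams, path, ref_affine, ref_dim) {
  vox <- sqrt(colSums(ref_affine[1:3, 1:3]^2))
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- raw(1000)
  hdr[1:6] <- writeBin(c(charToRaw("TRACK"), as.raw(0)), raw())
  put <- function(off, raws) hdr[(off + 1):(off + length(raws))] <<- raws
  put(6, writeBin(as.integer(ref_dim), raw(), 2, endian = "little"))
  put(12, writeBin(as.double(vox), raw(), 4, endian = "little"))
  put(24, writeBin(as.double(c(0, 0, 0)), raw(), 4, endian = "little"))
  # n_scalars (36) and n_properties (238) stay 0
  put(440, writeBin(as.double(t(ref_affine)), raw(), 4, endian = "little"))
  put(948, charToRaw("RAS"))  # voxel_order
  put(988, writeBin(n_streamlines(streams), raw(), 4, endian = "little"))
  put(992, writeBin(2L, raw(), 4, endian = "little"))
  put(996, writeBin(1000L, raw(), 4, endian = "little"))
  writeBin(hdr, con)
  inv <- solve(ref_affine)
  for (i in seq_len(n_streamlines(streams))) {
    pts <- streamline_points(streams, i)
    vx <- t(inv[1:3, 1:3] %*% t(pts) + inv[1:3, 4])  # voxel
    vmm <- sweep(vx + 0.5, 2, vox, `*`)              # voxel-mm, half-voxel shift
    writeBin(nrow(pts), con, 4, endian = "little")
    writeBin(as.double(t(vmm)), con, 4, endian = "little")
  }
  invisible(path)
}

#' @rdname write_trk
#' @export
read_trk <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 1000)
  if (!identical(rawToChar(hdr[1:5]), "TRACK"))
    abort_data(sprintf("read_trk: %s is not a TRK file", path))
  vox <- readBin(hdr[13:24], "double", 3, 4, endian = "little")
  aff <- matrix(readBin(hdr[441:504], "double", 16, 4, endian = "little"), 4, 4, byrow = TRUE)
  n_scalars <- readBin(hdr[37:38], "integer", 1, 2, endian = "little")
  n_props <- readBin(hdr[239:240], "integer", 1, 2, endian = "little")
  version <- readBin(hdr[993:996], "integer", 1, 4, endian = "little")
  if (version >= 2 && abs(aff[4, 4]) < .Machine$double.eps)
    abort_data("read_trk: header vox_to_ras matrix is unset")
  lst <- list()
  repeat {
    np <- readBin(con, "integer", 1, 4, endian = "little")
    if (!length(np)) break
    vals <- readBin(con, "double", np * (3 + n_scalars), 4, endian = "little")
    if (n_props > 0) readBin(con, "double", n_props, 4, endian = "little")
    m <- matrix(vals, ncol = 3 + n_scalars, byrow = TRUE)[, 1:3, drop = FALSE]
    vx <- sweep(m, 2, vox, `/`) - 0.5
    lst[[length(lst) + 1L]] <- t(aff[1:3, 1:3] %*% t(vx) + aff[1:3, 4])
  }
  from_polylines(lst)
}
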