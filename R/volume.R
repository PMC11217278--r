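#' Scalar volume: a 3-D grid with a voxel-to-world affine
#'
#' The basic image container: a numeric 3-D array plus a 4x4 affine mapping
#' 0-based voxel indices (i, j, k) to world coordinates in mm, NIfTI style.
#' Carries MD maps (mm^2/s), FA maps (unitless), probability maps, or integer
#' label volumes.
#'
#' @param data numeric 3-D array.
#' @param affine 4x4 voxel-to-world matrix (last row 0 0 0 1).
#' @param kind free-text tag ("MD", "FA", "prob", "label", ...).
#' @return an object of class `scalar_volume`.
#' @export
scalar_volume <- function(data, affine = diag(4), kind = "scalar") {
  if (length(dim(data)) != 3L) abort_data("scalar_volume: data must be a 3-D array")
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L))) abort_data("scalar_volume: affine must be 4x4")
  if (max(abs(affine[4, ] - c(0, 0, 0, 1))) > 1e-8)
    abort_data("scalar_volume: affine last row must be (0,0,0,1)")
  structure(list(data = data, affine = affine, kind = kind), class = "scalar_volume")
}

#' @export
print.scalar_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<scalar_volume [%s]> %dx%dx%d, voxel %s mm, range [%g, %g]\n",
              x$kind, d[1], d[2], d[3],
              paste(signif(voxel_size(x), 4), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

#' @rdname scalar_volume
#' @param x a `scalar_volume`.
#' @export
voxel_size <- function(x) sqrt(colSums(x$affine[1:3, 1:3]^2))

same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$data), dim(b$data)) && max(abs(a$affine - b$affine)) <= tol
}

#' Convert between voxel indices and world coordinates
#'
#' Voxel indices are 0-based (NIfTI convention); world coordinates are mm.
#'
#' @param vol a `scalar_volume`.
#' @param pts n x 3 matrix.
#' @return n x 3 matrix of mapped coordinates.
#' @export
voxel_to_world <- function(vol, pts) {
  pts <- rbind_pts(pts)
  t(vol$affine[1:3, 1:3] %*% t(pts) + vol$affine[1:3, 4])
}

#' @rdname voxel_to_world
#' @export
world_to_voxel <- function(vol, pts) {
  pts <- rbind_pts(pts)
  inv <- solve(vol$affine)
  t(inv[1:3, 1:3] %*% t(pts) + inv[1:3, 4])
}

rbind_pts <- function(pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 3)
  storage.mode(pts) <- "double"
  pts
}

#' Sample a scalar volume at world coordinates
#'
#' Trilinear (default) or nearest-neighbour interpolation. Points outside the
#' grid return `NA`.
#'
#' @param vol a `scalar_volume`.
#' @param pts n x 3 world-mm matrix.
#' @param interpolation "trilinear" or "nearest".
#' @return numeric vector of length n (`NA` outside the grid).
#' @export
sample_volume <- function(vol, pts, interpolation = c("trilinear", "nearest")) {
  interpolation <- match.arg(interpolation)
  v <- world_to_voxel(vol, pts)
  d <- dim(vol$data)
  if (interpolation == "nearest") {
    idx <- round(v)
    ok <- idx[, 1] >= 0 & idx[, 1] <= d[1] - 1 &
          idx[, 2] >= 0 & idx[, 2] <= d[2] - 1 &
          idx[, 3] >= 0 & idx[, 3] <= d[3] - 1
    out <- rep(NA_real_, nrow(v))
    if (any(ok)) out[ok] <- vol$data[cbind(idx[ok, 1] + 1, idx[ok, 2] + 1, idx[ok, 3] + 1)]
    return(out)
  }
  # trilinear: valid only when the full 2x2x2 neighbourhood exists
  f <- floor(v)
  w <- v - f
  ok <- f[, 1] >= 0 & f[, 1] <= d[1] - 2 &
        f[, 2] >= 0 & f[, 2] <= d[2] - 2 &
        f[, 3] >= 0 & f[, 3] <= d[3] - 2
  # points exactly on the far face are still inside
  hi <- v[, 1] == d[1] - 1 | v[, 2] == d[2] - 1 | v[, 3] == d[3] - 1
  on_face <- !ok & hi &
    v[, 1] >= 0 & v[, 1] <= d[1] - 1 &
    v[, 2] >= 0 & v[, 2] <= d[2] - 1 &
    v[, 3] >= 0 & v[, 3] <= d[3] - 1
  if (any(on_face)) {
    f[on_face, ] <- pmin(f[on_face, , drop = FALSE],
                         matrix(d - 2, sum(on_face), 3, byrow = TRUE))
    w[on_face, ] <- v[on_face, , drop = FALSE] - f[on_face, , drop = FALSE]
    ok <- ok | on_face
  }
  out <- rep(NA_real_, nrow(v))
  if (any(ok)) {
    fi <- f[ok, , drop = FALSE] + 1  # 1-based corner
    wx <- w[ok, 1]; wy <- w[ok, 2]; wz <- w[ok, 3]
    g <- vol$data
    c000 <- g[cbind(fi[, 1],     fi[, 2],     fi[, 3])]
    c100 <- g[cbind(fi[, 1] + 1, fi[, 2],     fi[, 3])]
    c010 <- g[cbind(fi[, 1],     fi[, 2] + 1, fi[, 3])]
    c110 <- g[cbind(fi[, 1] + 1, fi[, 2] + 1, fi[, 3])]
    c001 <- g[cbind(fi[, 1],     fi[, 2],     fi[, 3] + 1)]
    c101 <- g[cbind(fi[, 1] + 1, fi[, 2],     fi[, 3] + 1)]
    c011 <- g[cbind(fi[, 1],     fi[, 2] + 1, fi[, 3] + 1)]
    c111 <- g[cbind(fi[, 1] + 1, fi[, 2] + 1, fi[, 3] + 1)]
    out[ok] <- (1 - wz) * ((1 - wy) * ((1 - wx) * c000 + wx * c100) +
                                 wy  * ((1 - wx) * c010 + wx * c110)) +
                     wz  * ((1 - wy) * ((1 - wx) * c001 + wx * c101) +
                                 wy  * ((1 - wx) * c011 + wx * c111))
  }
  out
}

#' Upsample a volume by an integer-free percentage with trilinear interpolation
#'
#' "Resampling by 200%" doubles the grid resolution (halves the voxel size);
#' the field of view is preserved and the affine updated accordingly.
#'
#' @param vol a `scalar_volume`.
#' @param pct resampling percentage (>= 100); 100 is a no-op.
#' @return a `scalar_volume` on the finer grid.
#' @export
upsample_volume <- function(vol, pct = 200) {
  if (pct < 100) abort_config("upsample_volume: pct must be >= 100")
  if (pct == 100) return(vol)
  s <- pct / 100
  d <- dim(vol$data)
  nd <- pmax(2L, as.integer(round((d - 1) * s)) + 1L)
  # new voxel i' maps to old fractional index i' * (d-1)/(nd-1)
  sc <- (d - 1) / (nd - 1)
  gi <- (seq_len(nd[1]) - 1) * sc[1]
  gj <- (seq_len(nd[2]) - 1) * sc[2]
  gk <- (seq_len(nd[3]) - 1) * sc[3]
  pts <- as.matrix(expand.grid(i = gi, j = gj, k = gk))
  wpts <- voxel_to_world(vol, pts)
  vals <- sample_volume(vol, wpts, "trilinear")
  newaff <- vol$affine
  newaff[1:3, 1:3] <- sweep(vol$affine[1:3, 1:3], 2, sc, `*`)
  scalar_volume(array(vals, nd), newaff, vol$kind)
}
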