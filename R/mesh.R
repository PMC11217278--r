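#' Triangulated structure surface
#'
#' @param vertices V x 3 matrix of world-mm coordinates.
#' @param faces F x 3 integer matrix of 1-based vertex indices.
#' @param structure one of "VTA", "SNc", "striatum" (or any tag).
#' @param hemisphere "L", "R" or NA.
#' @param provenance list recording threshold, upsample factor, decimation.
#' @return an object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces, structure = NA_character_,
                         hemisphere = NA_character_, provenance = list()) {
  vertices <- rbind_pts(vertices)
  faces <- matrix(as.integer(faces), ncol = 3)
  if (nrow(faces) && max(faces) > nrow(vertices))
    abort_data("surface_mesh: face index exceeds vertex count")
  structure(list(vertices = vertices, faces = faces, structure = structure,
                 hemisphere = hemisphere, labels = NULL, provenance = provenance),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh %s/%s> %d vertices, %d faces, area %.2f mm^2\n",
              x$structure, x$hemisphere, nrow(x$vertices), nrow(x$faces),
              mesh_area(x)))
  invisible(x)
}

#' Total surface area and enclosed volume of a mesh
#'
#' Volume uses the divergence theorem (one-sixth sum of signed triple
#' products), so it requires consistent outward orientation — which
#' [extract_surface()] guarantees.
#'
#' @param mesh a `surface_mesh`.
#' @return area in mm^2 / volume in mm^3.
#' @export
mesh_area <- function(mesh) {
  f <- mesh$faces
  if (!nrow(f)) return(0)
  a <- mesh$vertices[f[, 1], , drop = FALSE]
  b <- mesh$vertices[f[, 2], , drop = FALSE]
  cc <- mesh$vertices[f[, 3], , drop = FALSE]
  cr <- cross3(b - a, cc - a)
  sum(sqrt(rowSums(cr^2))) / 2
}

#' @rdname mesh_area
#' @export
mesh_volume <- function(mesh) {
  f <- mesh$faces
  if (!nrow(f)) return(0)
  a <- mesh$vertices[f[, 1], , drop = FALSE]
  b <- mesh$vertices[f[, 2], , drop = FALSE]
  cc <- mesh$vertices[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
      a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
      a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])) / 6
}

cross3 <- function(u, v) {
  cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
        u[, 3] * v[, 1] - u[, 1] * v[, 3],
        u[, 1] * v[, 2] - u[, 2] * v[, 1])
}

# --- marching tetrahedra ----------------------------------------------------
# Each grid cube is split into six tetrahedra sharing the main diagonal
# (corner 0 to corner 6); the split is mirror-consistent across cube faces, so
# the extracted surface is watertight. Edge intersections are linearly
# interpolated; triangle orientation is fixed numerically so normals point
# from the inside (> threshold) region outward.

MT_CORNERS <- rbind(  # 0-based (di, dj, dk) offsets of cube corners 1..8
  c(0,0,0), c(1,0,0), c(1,1,0), c(0,1,0),
  c(0,0,1), c(1,0,1), c(1,1,1), c(0,1,1))
MT_TETS <- rbind(  # 1-based cube-corner ids; all share the 1-7 diagonal
  c(1,2,3,7), c(1,3,4,7), c(1,4,8,7),
  c(1,8,5,7), c(1,5,6,7), c(1,6,2,7))

marching_tetrahedra <- function(data, threshold) {
  d <- dim(data)
  inside <- data > threshold
  ni <- d[1] - 1L; nj <- d[2] - 1L; nk <- d[3] - 1L
  # per-cube inside count over the 8 corners
  cnt <- array(0L, c(ni, nj, nk))
  for (c8 in 1:8) {
    o <- MT_CORNERS[c8, ]
    cnt <- cnt + inside[(1 + o[1]):(ni + o[1]), (1 + o[2]):(nj + o[2]),
                        (1 + o[3]):(nk + o[3])]
  }
  act <- which(cnt > 0L & cnt < 8L)
  if (!length(act)) return(list(vertices = matrix(0, 0, 3), faces = matrix(0L, 0, 3)))
  ak <- (act - 1L) %/% (ni * nj)
  aj <- ((act - 1L) %% (ni * nj)) %/% ni
  ai <- (act - 1L) %% ni                     # 0-based cube origin
  # accumulators: canonical node pairs per triangle corner + interp weights
  E1a <- E1b <- E2a <- E2b <- E3a <- E3b <- integer(0)
  FLIPREF <- NULL  # per-triangle outward reference direction (n x 3)
  lin <- function(i0, j0, k0) i0 + j0 * d[1] + k0 * d[1] * d[2] + 1L  # 1-based linear
  for (tt in seq_len(nrow(MT_TETS))) {
    cid <- MT_TETS[tt, ]
    nod <- vals <- vector("list", 4)
    for (q in 1:4) {
      o <- MT_CORNERS[cid[q], ]
      nod[[q]] <- lin(ai + o[1], aj + o[2], ak + o[3])
      vals[[q]] <- data[nod[[q]]]
    }
    ins <- cbind(vals[[1]] > threshold, vals[[2]] > threshold,
                 vals[[3]] > threshold, vals[[4]] > threshold)
    code <- ins %*% c(1L, 2L, 4L, 8L)
    for (cs in 1:14) {
      sel <- which(code == cs)
      if (!length(sel)) next
      bits <- as.logical(bitwAnd(cs, c(1L, 2L, 4L, 8L)))
      inn <- which(bits); out <- which(!bits)
      n_of <- function(q) nod[[q]][sel]
      # outward reference: mean(outside corners) - mean(inside corners), in
      # 0-based voxel coords
      pos_of <- function(q) {
        l <- nod[[q]][sel] - 1L
        cbind(l %% d[1], (l %/% d[1]) %% d[2], l %/% (d[1] * d[2]))
      }
      pin <- Reduce(`+`, lapply(inn, pos_of)) / length(inn)
      pout <- Reduce(`+`, lapply(out, pos_of)) / length(out)
      ref <- pout - pin
      if (length(inn) == 1L || length(inn) == 3L) {
        apex <- if (length(inn) == 1L) inn else out
        oth <- setdiff(1:4, apex)
        tri <- list(c(apex, oth[1]), c(apex, oth[2]), c(apex, oth[3]))
        E1a <- c(E1a, n_of(tri[[1]][1])); E1b <- c(E1b, n_of(tri[[1]][2]))
        E2a <- c(E2a, n_of(tri[[2]][1])); E2b <- c(E2b, n_of(tri[[2]][2]))
        E3a <- c(E3a, n_of(tri[[3]][1])); E3b <- c(E3b, n_of(tri[[3]][2]))
        FLIPREF <- rbind(FLIPREF, ref)
      } else {
        # two in, two out: quad (a,c) (a,d) (b,d) (b,c) -> two triangles
        a <- inn[1]; b <- inn[2]; cc <- out[1]; dd <- out[2]
        q1a <- n_of(a); q1b <- n_of(cc)
        q2a <- n_of(a); q2b <- n_of(dd)
        q3a <- n_of(b); q3b <- n_of(dd)
        q4a <- n_of(b); q4b <- n_of(cc)
        E1a <- c(E1a, q1a, q1a); E1b <- c(E1b, q1b, q1b)
        E2a <- c(E2a, q2a, q3a); E2b <- c(E2b, q2b, q3b)
        E3a <- c(E3a, q3a, q4a); E3b <- c(E3b, q3b, q4b)
        FLIPREF <- rbind(FLIPREF, ref, ref)
      }
    }
  }
  if (!length(E1a)) return(list(vertices = matrix(0, 0, 3), faces = matrix(0L, 0, 3)))
  # canonicalise node pairs so shared edges weld exactly
  canon <- function(a, b) {
    sw <- a > b
    list(lo = ifelse(sw, b, a), hi = ifelse(sw, a, b))
  }
  c1 <- canon(E1a, E1b); c2 <- canon(E2a, E2b); c3 <- canon(E3a, E3b)
  lo <- c(c1$lo, c2$lo, c3$lo); hi <- c(c1$hi, c2$hi, c3$hi)
  key <- paste(lo, hi)
  uk <- !duplicated(key)
  vid <- match(key, key[uk])
  ulo <- lo[uk]; uhi <- hi[uk]
  s <- (threshold - data[ulo]) / (data[uhi] - data[ulo])
  p_lo <- cbind((ulo - 1L) %% d[1], ((ulo - 1L) %/% d[1]) %% d[2], (ulo - 1L) %/% (d[1] * d[2]))
  p_hi <- cbind((uhi - 1L) %% d[1], ((uhi - 1L) %/% d[1]) %% d[2], (uhi - 1L) %/% (d[1] * d[2]))
  verts <- p_lo + s * (p_hi - p_lo)
  # weld by position too: an intersection exactly on a grid node is reached
  # from several distinct edges (s = 0 or 1) and must collapse to one vertex
  pkey <- paste(round(verts[, 1], 9), round(verts[, 2], 9), round(verts[, 3], 9))
  puk <- !duplicated(pkey)
  pid <- match(pkey, pkey[puk])
  verts <- verts[puk, , drop = FALSE]
  vid <- pid[vid]
  ntri <- length(E1a)
  faces <- cbind(vid[1:ntri], vid[ntri + (1:ntri)], vid[2 * ntri + (1:ntri)])
  # orient: normal should align with the outward reference
  v1 <- verts[faces[, 2], , drop = FALSE] - verts[faces[, 1], , drop = FALSE]
  v2 <- verts[faces[, 3], , drop = FALSE] - verts[faces[, 1], , drop = FALSE]
  nrm <- cross3(v1, v2)
  flip <- rowSums(nrm * FLIPREF) < 0
  faces[flip, c(2, 3)] <- faces[flip, c(3, 2)]
  # drop degenerate (zero-area or repeated-vertex) faces
  dg <- faces[, 1] == faces[, 2] | faces[, 1] == faces[, 3] | faces[, 2] == faces[, 3]
  ar <- sqrt(rowSums(cross3(v1, v2)^2)) / 2
  keep <- !dg & ar > 1e-12
  list(vertices = verts, faces = faces[keep, , drop = FALSE])
}

#' Extract a structure surface from a probability volume
#'
#' Follows the atlas mesh-construction recipe: optional trilinear upsampling
#' of the probability map, isosurfacing at the given intensity, then optional
#' decimation removing a fraction of vertices. The defaults for the striatum
#' are `threshold = 0.5, upsample_pct = 100, decimate_fraction = 0.25`; for
#' the small VTA and SNc, `threshold = 0.3, upsample_pct = 200,
#' decimate_fraction = 0` (upsample first, no decimation).
#'
#' @param prob a probability [scalar_volume()] (values in `[0, 1]`).
#' @param threshold isosurface intensity, in (0, 1).
#' @param upsample_pct resampling percentage, >= 100.
#' @param decimate_fraction fraction of vertices to remove, in `[0, 1)`.
#' @param structure,hemisphere tags stored on the mesh.
#' @return a [surface_mesh()] in world mm with provenance recorded.
#' @export
extract_surface <- function(prob, threshold = 0.5, upsample_pct = 100,
                            decimate_fraction = 0,
                            structure = NA_character_, hemisphere = NA_character_) {
  if (threshold <= 0 || threshold >= 1) abort_config("extract_surface: threshold must be in (0, 1)")
  if (decimate_fraction < 0 || decimate_fraction >= 1)
    abort_config("extract_surface: decimate_fraction must be in [0, 1)")
  if (upsample_pct < 100) abort_config("extract_surface: upsample_pct must be >= 100")
  vol <- upsample_volume(prob, upsample_pct)
  if (!any(vol$data > threshold))
    abort_data(sprintf("empty structure: no voxel above threshold %g for %s/%s",
                       threshold, structure %||% "?", hemisphere %||% "?"))
  mt <- marching_tetrahedra(vol$data, threshold)
  verts <- voxel_to_world(vol, mt$vertices)
  mesh <- surface_mesh(verts, mt$faces, structure, hemisphere,
                       provenance = list(threshold = threshold,
                                         upsample_pct = upsample_pct,
                                         decimate_fraction = decimate_fraction))
  if (decimate_fraction > 0) mesh <- decimate_mesh(mesh, decimate_fraction)
  mesh
}

#' Decimate a mesh by edge collapse
#'
#' Quadric-error-metric decimation: each vertex accumulates the quadric of its
#' incident face planes; edges are collapsed cheapest-first to their midpoint
#' until exactly `ceiling((1 - fraction) * V)` vertices remain.
#'
#' @param mesh a [surface_mesh()].
#' @param fraction fraction of vertices to remove, in `[0, 1)`.
#' @return the decimated mesh (provenance updated).
#' @export
decimate_mesh <- function(mesh, fraction) {
  if (fraction < 0 || fraction >= 1) abort_config("decimate_mesh: fraction must be in [0, 1)")
  V <- nrow(mesh$vertices)
  target <- as.integer(ceiling((1 - fraction) * V))
  if (target >= V) return(mesh)
  pos <- mesh$vertices
  faces <- mesh$faces
  # per-vertex quadrics from face planes
  Q <- vector("list", V)
  for (v in seq_len(V)) Q[[v]] <- matrix(0, 4, 4)
  a <- pos[faces[, 1], , drop = FALSE]
  b <- pos[faces[, 2], , drop = FALSE]
  cc <- pos[faces[, 3], , drop = FALSE]
  nrm <- cross3(b - a, cc - a)
  nl <- sqrt(rowSums(nrm^2)); nl[nl == 0] <- 1
  nrm <- nrm / nl
  dpl <- -rowSums(nrm * a)
  for (f in seq_len(nrow(faces))) {
    p <- c(nrm[f, ], dpl[f])
    K <- tcrossprod(p)
    for (v in faces[f, ]) Q[[v]] <- Q[[v]] + K
  }
  ea <- c(faces[, 1], faces[, 2], faces[, 3])
  eb <- c(faces[, 2], faces[, 3], faces[, 1])
  sw <- ea > eb; tmp <- ea[sw]; ea[sw] <- eb[sw]; eb[sw] <- tmp
  ek <- paste(ea, eb)
  keep <- !duplicated(ek)
  ea <- ea[keep]; eb <- eb[keep]
  edge_cost <- function(i) {
    m <- c((pos[ea[i], ] + pos[eb[i], ]) / 2, 1)
    qq <- Q[[ea[i]]] + Q[[eb[i]]]
    as.numeric(m %*% qq %*% m)
  }
  cost <- vapply(seq_along(ea), edge_cost, 0)
  alive_v <- rep(TRUE, V)
  alive_f <- rep(TRUE, nrow(faces))
  n_alive <- V
  while (n_alive > target && any(is.finite(cost))) {
    i <- which.min(cost)
    u <- ea[i]; v <- eb[i]
    if (!alive_v[u] || !alive_v[v] || u == v) { cost[i] <- Inf; next }
    pos[u, ] <- (pos[u, ] + pos[v, ]) / 2
    Q[[u]] <- Q[[u]] + Q[[v]]
    alive_v[v] <- FALSE
    n_alive <- n_alive - 1L
    # remap faces and edges v -> u; kill degenerates
    hitf <- alive_f & (faces[, 1] == v | faces[, 2] == v | faces[, 3] == v)
    faces[hitf, ][faces[hitf, , drop = FALSE] == v] <- u
    degf <- alive_f & (faces[, 1] == faces[, 2] | faces[, 1] == faces[, 3] |
                       faces[, 2] == faces[, 3])
    alive_f[degf] <- FALSE
    hit <- ea == v | eb == v
    ea[hit & ea == v] <- u
    eb[hit & eb == v] <- u
    sw2 <- hit & (ea > eb)
    tmp <- ea[sw2]; ea[sw2] <- eb[sw2]; eb[sw2] <- tmp
    self <- ea == eb
    cost[self] <- Inf
    upd <- which((ea == u | eb == u) & !self)
    if (length(upd)) cost[upd] <- vapply(upd, edge_cost, 0)
  }
  # compact
  newid <- cumsum(alive_v)
  fkeep <- faces[alive_f, , drop = FALSE]
  out <- surface_mesh(pos[alive_v, , drop = FALSE],
                      matrix(newid[fkeep], ncol = 3),
                      mesh$structure, mesh$hemisphere, mesh$provenance)
  out$provenance$decimated_to <- nrow(out$vertices)
  out
}

#' Transform mesh vertices
#'
#' Accepts either a 4x4 affine or a dense displacement field given as a list
#' of three [scalar_volume()]s (`dx`, `dy`, `dz`, in mm) sampled trilinearly
#' at each vertex. Faces are unchanged.
#'
#' @param mesh a [surface_mesh()].
#' @param transform 4x4 matrix (must be invertible) or `list(dx=, dy=, dz=)`.
#' @return the transformed mesh.
#' @export
apply_transform <- function(mesh, transform) {
  if (is.matrix(transform)) {
    if (!all(dim(transform) == c(4, 4))) abort_config("apply_transform: affine must be 4x4")
    dt <- det(transform[1:3, 1:3])
    if (!is.finite(dt) || abs(dt) < 1e-12) abort_config("apply_transform: affine is not invertible")
    mesh$vertices <- t(transform[1:3, 1:3] %*% t(mesh$vertices) + transform[1:3, 4])
  } else if (is.list(transform) && all(c("dx", "dy", "dz") %in% names(transform))) {
    disp <- cbind(sample_volume(transform$dx, mesh$vertices),
                  sample_volume(transform$dy, mesh$vertices),
                  sample_volume(transform$dz, mesh$vertices))
    if (anyNA(disp)) abort_data("apply_transform: vertex outside displacement field")
    mesh$vertices <- mesh$vertices + disp
  } else abort_config("apply_transform: transform must be a 4x4 affine or list(dx, dy, dz)")
  mesh
}

#' Seeding spheres centred at mesh vertices
#'
#' One tractography seeding sphere per vertex; default radius 0.5 mm.
#'
#' @param mesh a [surface_mesh()].
#' @param radius_mm sphere radius in mm (> 0).
#' @return a data.frame with columns `vertex`, `x`, `y`, `z`, `radius_mm`.
#' @export
seed_spheres <- function(mesh, radius_mm = 0.5) {
  if (radius_mm <= 0) abort_config("seed_spheres: radius must be > 0")
  data.frame(vertex = seq_len(nrow(mesh$vertices)),
             x = mesh$vertices[, 1], y = mesh$vertices[, 2], z = mesh$vertices[, 3],
             radius_mm = radius_mm)
}

# Euler characteristic per connected component (V - E + F); 2 for each closed
# genus-0 component. Used by tests to check mesh closure.
mesh_euler <- function(mesh) {
  f <- mesh$faces
  ea <- c(f[, 1], f[, 2], f[, 3]); eb <- c(f[, 2], f[, 3], f[, 1])
  key <- paste(pmin(ea, eb), pmax(ea, eb))
  nE <- length(unique(key))
  # components via union-find over edges
  parent <- seq_len(nrow(mesh$vertices))
  findp <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  for (i in seq_along(ea)) {
    ra <- findp(ea[i]); rb <- findp(eb[i])
    if (ra != rb) parent[ra] <- rb
  }
  comp <- vapply(seq_along(parent), findp, 0L)
  used <- sort(unique(c(f)))
  comp_of_face <- comp[f[, 1]]
  vapply(unique(comp[used]), function(cmp) {
    vv <- sum(comp[used] == cmp)
    ff <- sum(comp_of_face == cmp)
    ee <- length(unique(key[comp[ea] == cmp]))
    vv - ee + ff
  }, 0)
}

#' Read and write meshes as ASCII PLY
#'
#' @param mesh a [surface_mesh()].
#' @param path file path.
#' @return `path` / a `surface_mesh`.
#' @export
write_ply <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("comment subparc %s %s", mesh$structure, mesh$hemisphere),
               sprintf("element vertex %d", nrow(mesh$vertices)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(mesh$faces)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(apply(format(mesh$vertices, digits = 9, trim = TRUE, scientific = FALSE),
                   1, paste, collapse = " "), con)
  writeLines(paste(3, mesh$faces[, 1] - 1, mesh$faces[, 2] - 1, mesh$faces[, 3] - 1), con)
  invisible(path)
}

#' @rdname write_ply
#' @export
read_ply <- function(path) {
  lines <- readLines(path)
  if (lines[1] != "ply") abort_data(sprintf("read_ply: %s is not a PLY file", path))
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", lines, value = TRUE)[1]))
  nf <- as.integer(sub("element face ", "", grep("^element face", lines, value = TRUE)[1]))
  hdr_end <- which(lines == "end_header")[1]
  vl <- lines[(hdr_end + 1):(hdr_end + nv)]
  fl <- lines[(hdr_end + nv + 1):(hdr_end + nv + nf)]
  verts <- do.call(rbind, lapply(strsplit(vl, " "), function(s) as.numeric(s[1:3])))
  faces <- do.call(rbind, lapply(strsplit(fl, " "), function(s) as.integer(s[2:4]) + 1L))
  surface_mesh(verts, faces)
}
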