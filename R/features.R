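# Diffusion-microstructure features: bundle MD/FA (mean of the scalar map
# over voxels traversed by a subregion-to-target streamline bundle) and
# surface MD/FA (mean of the scalar map sampled at the subregion's surface
# vertices).

#' Extract the streamline bundle of a subregion
#'
#' Streamlines whose seed vertex carries the subregion's label AND whose
#' terminal cortical label equals that same target. `subregion = "total"`
#' takes the union over all assigned subregions.
#'
#' @param streams a [streamline_set()] with `seed_vertex`; terminal labels
#'   are computed from `cortical_labels` if not already attached.
#' @param parc a `vertex_parcellation`.
#' @param subregion 1-based target id, or "total".
#' @param cortical_labels label [scalar_volume()] (needed when terminal
#'   labels are not attached).
#' @return the filtered [streamline_set()].
#' @export
extract_bundle <- function(streams, parc, subregion, cortical_labels = NULL) {
  if (is.null(streams$seed_vertex))
    abort_data("extract_bundle: streamlines lack seed-vertex annotations")
  tl <- streams$terminal_label
  if (is.null(tl)) {
    if (is.null(cortical_labels))
      abort_data("extract_bundle: need terminal labels or a cortical label volume")
    tl <- terminal_label(streams, cortical_labels)
  }
  vlab <- parc$label[streams$seed_vertex]
  if (identical(subregion, "total")) {
    keep <- vlab > 0L & tl == vlab
  } else {
    subregion <- as.integer(subregion)
    if (is.na(subregion) || subregion < 1L || subregion > max(1L, ncol_counts(parc)))
      abort_config(sprintf("extract_bundle: unknown subregion id '%s'", subregion))
    keep <- vlab == subregion & tl == subregion
  }
  subset_streamlines(streams, which(keep), tl)
}

# upper bound on valid target ids for a parcellation (labels observed or any
# positive id; parcellation does not store T so accept ids up to 6)
ncol_counts <- function(parc) max(6L, parc$label)

subset_streamlines <- function(streams, idx, tl = NULL) {
  if (!length(idx))
    return(streamline_set(matrix(0, 0, 3), integer(0),
                          seed_vertex = integer(0), terminal_label = integer(0)))
  rows <- sequence(streams$lengths[idx], from = streams$offsets[idx] + 1L)
  streamline_set(streams$coords[rows, , drop = FALSE], streams$lengths[idx],
                 seed_vertex = streams$seed_vertex[idx],
                 terminal_label = if (!is.null(tl)) tl[idx] else streams$terminal_label[idx])
}

#' Voxelise a streamline bundle
#'
#' A voxel enters the mask iff at least one streamline, resampled at a fine
#' arc-length step (default one tenth of the smallest voxel size, well under
#' the half-voxel contract), has a point inside it.
#'
#' @param bundle a [streamline_set()].
#' @param grid a [scalar_volume()] supplying the grid geometry.
#' @param step_frac resampling step as a fraction of the voxel size (<= 0.5).
#' @return logical array (the bundle mask).
#' @export
voxelize_bundle <- function(bundle, grid, step_frac = 0.1) {
  d <- dim(grid$data)
  mask <- array(FALSE, d)
  if (n_streamlines(bundle) == 0L) return(mask)
  step <- min(voxel_size(grid)) * step_frac
  pts <- resample_polylines(bundle, step)
  v <- round(world_to_voxel(grid, pts))
  ok <- v[, 1] >= 0 & v[, 1] < d[1] & v[, 2] >= 0 & v[, 2] < d[2] &
        v[, 3] >= 0 & v[, 3] < d[3]
  if (any(ok)) mask[v[ok, 1] + v[ok, 2] * d[1] + v[ok, 3] * d[1] * d[2] + 1] <- TRUE
  mask
}

# dense resampling of all polylines at arc-length step `step`, vectorised
# over every segment of every streamline (original vertices are among the
# samples, so thin axis-aligned lines hit exactly their voxels)
resample_polylines <- function(streams, step) {
  co <- streams$coords
  last <- streams$offsets[-1]                  # last point of each streamline
  seg_a <- setdiff(seq_len(nrow(co)), last)    # segment start rows
  if (!length(seg_a)) return(co)
  a <- co[seg_a, , drop = FALSE]
  b <- co[seg_a + 1L, , drop = FALSE]
  len <- sqrt(rowSums((b - a)^2))
  nsub <- pmax(1L, as.integer(ceiling(len / step)))
  tot <- nsub + 1L
  ai <- rep.int(seq_along(nsub), tot)
  tt <- (sequence(tot) - 1) / nsub[ai]
  a[ai, , drop = FALSE] + tt * (b[ai, , drop = FALSE] - a[ai, , drop = FALSE])
}

#' Mean scalar over a bundle mask
#'
#' @param mask logical array from [voxelize_bundle()].
#' @param scalar a [scalar_volume()] on the same grid.
#' @return the arithmetic mean, or `NA` (with attribute `reason`) if the
#'   mask is empty.
#' @export
bundle_mean <- function(mask, scalar) {
  if (!identical(dim(mask), dim(scalar$data)))
    abort_data("bundle_mean: mask and scalar grids differ")
  if (!any(mask)) return(structure(NA_real_, reason = "empty bundle"))
  mean(scalar$data[mask])
}

#' Mean scalar over surface vertices
#'
#' Samples the scalar map at each vertex's world coordinate (trilinear by
#' default) and averages. Vertices falling outside the grid are excluded and
#' counted; if all fall outside the result is `NA`.
#'
#' @param mesh a [surface_mesh()].
#' @param vertex_set integer vertex indices (e.g. from
#'   [subregion_vertex_sets()]).
#' @param scalar a [scalar_volume()].
#' @param interpolation "trilinear" or "nearest".
#' @return mean value with attribute `n_outside`; `NA` if empty/all outside.
#' @export
surface_mean <- function(mesh, vertex_set, scalar,
                         interpolation = c("trilinear", "nearest")) {
  interpolation <- match.arg(interpolation)
  if (!length(vertex_set)) return(structure(NA_real_, reason = "empty vertex set"))
  vals <- sample_volume(scalar, mesh$vertices[vertex_set, , drop = FALSE], interpolation)
  n_out <- sum(is.na(vals))
  if (n_out == length(vals))
    return(structure(NA_real_, reason = "all vertices outside grid", n_outside = n_out))
  structure(mean(vals, na.rm = TRUE), n_outside = n_out)
}

#' Compute all features for one subject and one structure/hemisphere
#'
#' @param mesh a [surface_mesh()] for the structure/hemisphere.
#' @param parc its `vertex_parcellation`.
#' @param streams its seeded [streamline_set()].
#' @param cortical_labels label [scalar_volume()].
#' @param md,fa the subject's scalar maps.
#' @param interpolation surface sampling mode.
#' @return named numeric vector over the structure's feature grid rows
#'   (names without the structure prefix: e.g. "caudal_motor_surface_MD").
#' @export
structure_features <- function(mesh, parc, streams, cortical_labels, md, fa,
                               interpolation = "trilinear") {
  tg <- structure_targets(mesh$structure)
  sets <- subregion_vertex_sets(parc, length(tg))
  out <- c()
  for (sub in c("total", tg)) {
    sid <- if (sub == "total") "total" else match(sub, tg)
    vset <- if (sub == "total") sets$total else sets[[as.character(sid)]]
    bundle <- extract_bundle(streams, parc, if (sub == "total") "total" else sid,
                             cortical_labels)
    mask <- voxelize_bundle(bundle, md)
    for (met in c("MD", "FA")) {
      sc <- if (met == "MD") md else fa
      out[paste(sub, "bundle", met, sep = "_")] <- as.numeric(bundle_mean(mask, sc))
      out[paste(sub, "surface", met, sep = "_")] <-
        as.numeric(surface_mean(mesh, vset, sc, interpolation))
    }
  }
  out
}

#' Assemble the subject x feature table
#'
#' @param cohort a cohort table (one row per subject).
#' @param per_subject named list (by subject id) of lists with elements
#'   `meshes`, `parcs`, `streams` (each named "structure_hemisphere"), `md`,
#'   `fa`; missing modalities yield NA features with a warning.
#' @param cortical_labels label [scalar_volume()].
#' @param hemisphere_policy "average" (vertex-weighted L/R average, default)
#'   or "separate" (per-hemisphere columns).
#' @param interpolation surface sampling mode.
#' @return data.frame: subject column + numeric feature columns; attribute
#'   `provenance` records the parcellation parameters.
#' @export
build_feature_table <- function(cohort, per_subject, cortical_labels,
                                hemisphere_policy = c("average", "separate"),
                                interpolation = "trilinear") {
  hemisphere_policy <- match.arg(hemisphere_policy)
  rows <- list()
  prov <- NULL
  for (i in seq_len(nrow(cohort))) {
    sid <- cohort$subject[i]
    ps <- per_subject[[sid]]
    if (is.null(ps) || is.null(ps$md) || is.null(ps$fa)) {
      warning(sprintf("build_feature_table: subject %s missing a modality; row retained with NAs", sid))
      rows[[sid]] <- list(subject = sid)
      next
    }
    feat <- list(subject = sid)
    for (key in names(ps$meshes)) {
      mesh <- ps$meshes[[key]]
      parc <- ps$parcs[[key]]
      if (is.null(prov)) prov <- list(min_count = parc$min_count, tie_policy = parc$tie_policy,
                                      hemisphere_policy = hemisphere_policy,
                                      interpolation = interpolation)
      f <- structure_features(mesh, parc, ps$streams[[key]], cortical_labels,
                              ps$md, ps$fa, interpolation)
      st <- mesh$structure; hemi <- mesh$hemisphere
      nm <- if (hemisphere_policy == "separate") paste(st, hemi, names(f), sep = "_")
            else paste(st, names(f), sep = "_")
      if (hemisphere_policy == "average") {
        w <- nrow(mesh$vertices)
        for (j in seq_along(f)) {
          k <- nm[j]
          prev <- feat[[k]] %||% c(0, 0)
          feat[[k]] <- c(prev[1] + unname(f[j]) * w, prev[2] + w)
        }
      } else {
        for (j in seq_along(f)) feat[[nm[j]]] <- unname(f[j])
      }
    }
    if (hemisphere_policy == "average") {
      for (k in setdiff(names(feat), "subject"))
        feat[[k]] <- feat[[k]][1] / feat[[k]][2]
    }
    rows[[sid]] <- feat
  }
  cols <- unique(unlist(lapply(rows, names)))
  df <- data.frame(subject = vapply(rows, function(r) r$subject, ""),
                   stringsAsFactors = FALSE)
  for (k in setdiff(cols, "subject"))
    df[[k]] <- vapply(rows, function(r) { v <- r[[k]]; if (is.null(v)) NA_real_ else as.numeric(v) }, 0)
  rownames(df) <- NULL
  attr(df, "provenance") <- prov
  df
}

#' Write / read a feature table as CSV with a JSON sidecar
#'
#' Full-precision round trip; the sidecar records the column schema and the
#' parcellation provenance.
#'
#' @param df feature table from [build_feature_table()].
#' @param path CSV path (sidecar gets `.json` appended).
#' @return `path` / the re-read data.frame.
#' @export
write_feature_table <- function(df, path) {
  out <- df
  for (k in names(out)) if (is.numeric(out[[k]]))
    out[[k]] <- formatC(out[[k]], digits = 17, format = "g")
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  side <- list(columns = names(df), provenance = attr(df, "provenance") %||% list(),
               schema_version = "1")
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  side <- tryCatch(jsonlite::read_json(paste0(path, ".json")), error = function(e) NULL)
  if (!is.null(side)) attr(df, "provenance") <- side$provenance
  df
}
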