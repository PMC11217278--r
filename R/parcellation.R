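# Connectivity-based winner-take-all parcellation: each subcortical surface
# vertex is assigned to the cortical target receiving the most of its
# streamlines, subject to a minimum fibre-count limit that prevents
# assignment on low counts.

#' Terminal cortical label of streamlines
#'
#' The label of the voxel containing each streamline's final point (nearest
#' voxel under the label volume's affine); 0 for background or out-of-grid
#' terminations. Only the final point is used, not a terminal segment.
#'
#' @param streams a [streamline_set()] (or an n x 3 matrix of endpoints).
#' @param cortical_labels integer label [scalar_volume()].
#' @return integer vector of labels, one per streamline.
#' @export
terminal_label <- function(streams, cortical_labels) {
  ep <- if (inherits(streams, "streamline_set")) streamline_endpoints(streams)
        else rbind_pts(streams)
  lab <- sample_volume(cortical_labels, ep, "nearest")
  lab[is.na(lab)] <- 0
  as.integer(lab)
}

#' Count streamline connections per (seed vertex, cortical target)
#'
#' @param streams a [streamline_set()] with `seed_vertex` set.
#' @param cortical_labels label [scalar_volume()].
#' @param n_vertices number of mesh vertices (rows of the count matrix);
#'   defaults to `max(seed_vertex)`.
#' @param n_targets number of cortical targets (columns); defaults to the
#'   maximum label in the volume.
#' @return integer matrix `C[v, t]`; background terminations (label 0) are
#'   excluded from every column.
#' @export
count_connections <- function(streams, cortical_labels, n_vertices = NULL,
                              n_targets = NULL) {
  if (is.null(streams$seed_vertex))
    abort_data("count_connections: streamlines lack seed-vertex annotations")
  if (is.null(n_vertices)) n_vertices <- max(streams$seed_vertex, 0L)
  if (is.null(n_targets)) n_targets <- as.integer(max(cortical_labels$data))
  C <- matrix(0L, n_vertices, n_targets)
  if (n_streamlines(streams) == 0L) return(C)
  lab <- terminal_label(streams, cortical_labels)
  keep <- lab > 0L & lab <= n_targets
  if (any(keep)) {
    tab <- table(factor(streams$seed_vertex[keep], levels = seq_len(n_vertices)),
                 factor(lab[keep], levels = seq_len(n_targets)))
    C <- matrix(as.integer(tab), n_vertices, n_targets)
  }
  C
}

#' Winner-take-all vertex assignment
#'
#' Each vertex gets the target with the highest streamline count, provided
#' that count reaches `min_count`; otherwise it stays unassigned (0). Ties
#' are resolved by `tie_policy`: `"lowest"` (deterministic lowest target
#' index, the default), `"unassigned"` (ties stay 0), or `"random"` (seeded
#' uniform choice among the tied maxima).
#'
#' @param counts integer matrix `C[v, t]` from [count_connections()].
#' @param min_count minimum fibre count (>= 1; default 10 of 250 seeds).
#' @param tie_policy one of "lowest", "unassigned", "random".
#' @param seed RNG seed (used only by `tie_policy = "random"`).
#' @return an object of class `vertex_parcellation`: list(label =, min_count
#'   =, tie_policy =).
#' @export
assign_subregions <- function(counts, min_count = 10L,
                              tie_policy = c("lowest", "unassigned", "random"),
                              seed = 1L) {
  tie_policy <- match.arg(tie_policy)
  if (min_count < 1) abort_config("assign_subregions: min_count must be >= 1")
  counts <- as.matrix(counts)
  V <- nrow(counts)
  label <- integer(V)
  if (V > 0) {
    mx <- apply(counts, 1, max)
    win <- max.col(counts, ties.method = "first")  # lowest index among ties
    ntied <- rowSums(counts == mx)
    if (tie_policy == "unassigned") {
      win[ntied > 1L] <- 0L
    } else if (tie_policy == "random") {
      idx <- which(ntied > 1L & mx >= min_count)
      if (length(idx)) with_seed(seed, {
        for (v in idx) {
          tied <- which(counts[v, ] == mx[v])
          win[v] <- tied[sample.int(length(tied), 1L)]
        }
      })
    }
    label <- ifelse(mx >= min_count, win, 0L)
    label[win == 0L] <- 0L
  }
  structure(list(label = as.integer(label), min_count = as.integer(min_count),
                 tie_policy = tie_policy),
            class = "vertex_parcellation")
}

#' @export
print.vertex_parcellation <- function(x, ...) {
  cat(sprintf("<vertex_parcellation> %d vertices, %d unassigned, min_count %d, ties '%s'\n",
              length(x$label), sum(x$label == 0L), x$min_count, x$tie_policy))
  invisible(x)
}

#' Per-subregion vertex index sets
#'
#' @param parc a `vertex_parcellation`.
#' @param n_targets number of targets (defaults to max label).
#' @return list with one integer vector per target (named "1".."T"),
#'   `unassigned`, and `total` (all vertices, unassigned included).
#' @export
subregion_vertex_sets <- function(parc, n_targets = NULL) {
  if (is.null(n_targets)) n_targets <- max(parc$label, 1L)
  out <- lapply(seq_len(n_targets), function(t) which(parc$label == t))
  names(out) <- as.character(seq_len(n_targets))
  out$unassigned <- which(parc$label == 0L)
  out$total <- seq_along(parc$label)
  out
}

#' Paint a vertex parcellation into a label volume
#'
#' Nearest-vertex voxel painting restricted to voxels inside the structure
#' (probability above `mask_threshold`); used to export per-subregion masks.
#'
#' @param mesh a [surface_mesh()].
#' @param parc a `vertex_parcellation`.
#' @param prob probability [scalar_volume()] defining the structure extent.
#' @param mask_threshold probability level defining "inside".
#' @return a label [scalar_volume()].
#' @export
paint_parcellation <- function(mesh, parc, prob, mask_threshold = 0.5) {
  d <- dim(prob$data)
  idx <- which(prob$data >= mask_threshold)
  out <- array(0, d)
  if (length(idx)) {
    l <- idx - 1L
    vox <- cbind(l %% d[1], (l %/% d[1]) %% d[2], l %/% (d[1] * d[2]))
    W <- voxel_to_world(prob, vox)
    # nearest mesh vertex per voxel
    nn <- apply_nearest(W, mesh$vertices)
    out[idx] <- parc$label[nn]
  }
  scalar_volume(out, prob$affine, "label")
}

apply_nearest <- function(query, ref) {
  # chunked exact nearest neighbour (data sizes here are small)
  n <- nrow(query)
  out <- integer(n)
  step <- 2048L
  r2 <- rowSums(ref^2)
  for (s in seq(1L, n, by = step)) {
    e <- min(n, s + step - 1L)
    q <- query[s:e, , drop = FALSE]
    D <- outer(rowSums(q^2), r2, `+`) - 2 * q %*% t(ref)
    out[s:e] <- max.col(-D, ties.method = "first")
  }
  out
}
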