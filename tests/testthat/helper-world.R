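# Shared toy world: a small phantom whose blobs fit a 24^3 grid, with the
# atlas and one SNc mesh built once per test run.

toy_phantom <- function(seed = 1L) phantom_spec(
  grid_shape = c(24L, 24L, 24L),
  structures = list(
    striatum = list(centre = c(5, 1, 1), radius_mm = 4),
    SNc      = list(centre = c(4.5, -3, -3), radius_mm = 2.8),
    VTA      = list(centre = c(1.5, -3.5, -3.5), radius_mm = 2)),
  seed = seed)

.toy_cache <- new.env(parent = emptyenv())
toy_world <- function() {
  if (is.null(.toy_cache$w)) {
    spec <- toy_phantom()
    atlas <- generate_atlas(spec)
    mesh <- extract_surface(atlas$prob$SNc_R, 0.3, 100, 0, "SNc", "R")
    .toy_cache$w <- list(spec = spec, atlas = atlas, mesh = mesh)
  }
  .toy_cache$w
}

# analytic sphere probability field: exp(-log 2 (d/r)^2) so the 0.5 level is
# exactly at radius r
sphere_volume <- function(radius_mm, n = 33L, voxel = 1) {
  aff <- diag(4); diag(aff)[1:3] <- voxel
  aff[1:3, 4] <- -voxel * (n - 1) / 2
  g <- seq(0, n - 1) * voxel - voxel * (n - 1) / 2
  d2 <- outer(outer(g^2, g^2, `+`), g^2, `+`)
  scalar_volume(array(exp(-log(2) * d2 / radius_mm^2), c(n, n, n)), aff, "prob")
}

# tiny deterministic streamline set builder
mk_streams <- function(polylines, seed_vertex = NULL) {
  streamline_set(do.call(rbind, polylines), vapply(polylines, nrow, 0L),
                 seed_vertex = seed_vertex)
}
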