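test_that("extract_bundle equals a brute-force (seed label, terminal label) filter", {
  w <- toy_world()
  set.seed(13)
  V <- 30L
  polys <- lapply(1:150, function(i) rbind(runif(3, -10, 10), runif(3, -13, 13)))
  sv <- sample.int(V, 150, TRUE)
  st <- mk_streams(polys, seed_vertex = sv)
  lab <- terminal_label(st, w$atlas$cortical_labels)
  vlab <- sample(0:4, V, TRUE)
  parc <- structure(list(label = vlab, min_count = 1L, tie_policy = "lowest"),
                    class = "vertex_parcellation")
  for (sub in 1:4) {
    b <- extract_bundle(st, parc, sub, w$atlas$cortical_labels)
    brute <- which(vlab[sv] == sub & lab == sub)
    expect_identical(b$seed_vertex, sv[brute])
    expect_identical(n_streamlines(b), length(brute))
  }
  tot <- extract_bundle(st, parc, "total", w$atlas$cortical_labels)
  bruteT <- which(vlab[sv] > 0 & lab == vlab[sv])
  expect_identical(n_streamlines(tot), length(bruteT))
  expect_error(extract_bundle(st, parc, 99, w$atlas$cortical_labels),
               class = "subparc_config_error")
})

test_that("voxelisation: axis-aligned line hits exactly its voxels; empty bundle empty mask", {
  g <- scalar_volume(array(0, c(10, 10, 10)))
  st <- mk_streams(list(rbind(c(2, 5, 5), c(6, 5, 5))))  # through 5 voxel centres
  m <- voxelize_bundle(st, g)
  expect_identical(sum(m), 5L)
  expect_true(all(m[3:7, 6, 6]))
  empty <- streamline_set(matrix(0, 0, 3), integer(0))
  expect_identical(sum(voxelize_bundle(empty, g)), 0L)
})

test_that("voxelisation of curved streamlines matches dense brute-force sampling", {
  g <- scalar_volume(array(0, c(16, 16, 16)))
  set.seed(14)
  polys <- lapply(1:10, function(i) {
    t <- seq(0, 1, length.out = 5)
    cbind(2 + 11 * t, 7 + 5 * sin(pi * t * runif(1)), 2 + 11 * t^2)
  })
  st <- mk_streams(polys)
  m <- voxelize_bundle(st, g)
  # oracle: sample each segment at voxel/10 steps, mark nearest voxels
  oracle <- array(FALSE, dim(g$data))
  for (p in polys) for (s in seq_len(nrow(p) - 1)) {
    tt <- seq(0, 1, by = 0.1 / sqrt(sum((p[s + 1, ] - p[s, ])^2)) )
    pts <- outer(1 - tt, p[s, ]) + outer(tt, p[s + 1, ])
    v <- round(pts) + 1
    ok <- apply(v >= 1 & v <= 16, 1, all)
    oracle[v[ok, , drop = FALSE]] <- TRUE
  }
  expect_identical(m, oracle)
})

test_that("bundle_mean is the plain voxel mean and errors on grid mismatch", {
  g <- scalar_volume(array(7, c(4, 4, 4)))
  m <- array(FALSE, c(4, 4, 4)); m[1, 1, 1] <- m[2, 3, 4] <- TRUE
  expect_identical(bundle_mean(m, g), 7)
  g$data[1, 1, 1] <- 1; g$data[2, 3, 4] <- 3
  expect_identical(bundle_mean(m, g), 2)
  # random mask/map vs loop oracle
  set.seed(15)
  for (i in 1:20) {
    gg <- scalar_volume(array(rnorm(64), c(4, 4, 4)))
    mm <- array(runif(64) < 0.3, c(4, 4, 4))
    if (!any(mm)) next
    acc <- 0; k <- 0
    for (a in 1:4) for (b in 1:4) for (cc in 1:4) if (mm[a, b, cc]) {
      acc <- acc + gg$data[a, b, cc]; k <- k + 1
    }
    expect_equal(bundle_mean(mm, gg), acc / k)
  }
  expect_true(is.na(bundle_mean(array(FALSE, c(4, 4, 4)), g)))
  expect_error(bundle_mean(array(FALSE, c(3, 4, 4)), g), class = "subparc_data_error")
})

test_that("surface means: constants, outside handling, algebraic identity over subregions", {
  w <- toy_world()
  g <- w$atlas$prob$SNc_R
  cg <- scalar_volume(array(3.25, dim(g$data)), g$affine)
  expect_equal(as.numeric(surface_mean(w$mesh, 1:10, cg)), 3.25)
  # vertices pushed outside are excluded with a count
  m2 <- w$mesh; m2$vertices[1:3, 1] <- 1e5
  sm <- surface_mean(m2, 1:10, cg)
  expect_identical(attr(sm, "n_outside"), 3L)
  expect_equal(as.numeric(sm), 3.25)
  expect_true(is.na(surface_mean(m2, 1:3, cg)))
  # total mean = vertex-count-weighted mean over subregion + unassigned sets
  set.seed(16)
  vals <- scalar_volume(array(rnorm(prod(dim(g$data)), 1, 0.2), dim(g$data)), g$affine)
  lab <- sample(0:4, nrow(w$mesh$vertices), TRUE)
  parc <- structure(list(label = lab, min_count = 1L, tie_policy = "lowest"),
                    class = "vertex_parcellation")
  sets <- subregion_vertex_sets(parc, 4)
  tot <- as.numeric(surface_mean(w$mesh, sets$total, vals))
  parts <- c(sets[as.character(1:4)], list(sets$unassigned))
  wsum <- sum(vapply(parts, function(s) {
    if (!length(s)) 0 else as.numeric(surface_mean(w$mesh, s, vals)) * length(s)
  }, 0))
  expect_equal(tot, wsum / nrow(w$mesh$vertices), tolerance = 1e-12)
})

test_that("scale equivariance: scaling the map scales every bundle and surface mean", {
  w <- toy_world()
  prof <- truth_profile(w$spec, w$mesh, dominant = 0.85)
  st <- generate_streamlines(w$mesh, w$atlas$cortical_labels, prof, 20, seed = 17)
  C <- count_connections(st, w$atlas$cortical_labels, nrow(w$mesh$vertices), 4)
  parc <- assign_subregions(C, 3)
  maps <- generate_subject_maps(w$atlas, effect_spec(subject_sd = 0, voxel_sd = 0.02),
                                "HC", 18)
  f1 <- structure_features(w$mesh, parc, st, w$atlas$cortical_labels, maps$md, maps$fa)
  k <- 3.7
  md_k <- maps$md; md_k$data <- md_k$data * k
  fa_k <- maps$fa; fa_k$data <- fa_k$data * k
  f2 <- structure_features(w$mesh, parc, st, w$atlas$cortical_labels, md_k, fa_k)
  expect_equal(f2, f1 * k, tolerance = 1e-12)
})

test_that("closed loop: injected +10% caudal-motor shift is recovered through the pipeline", {
  w <- toy_world()
  prof <- truth_profile(w$spec, w$mesh, dominant = 0.85)
  st <- generate_streamlines(w$mesh, w$atlas$cortical_labels, prof, 25, seed = 19)
  C <- count_connections(st, w$atlas$cortical_labels, nrow(w$mesh$vertices), 4)
  parc <- assign_subregions(C, 4)
  eff <- effect_spec(shift = 0.10, subject_sd = 0, voxel_sd = 0)
  pat <- generate_subject_maps(w$atlas, eff, "iRBD", 20)
  f <- structure_features(w$mesh, parc, st, w$atlas$cortical_labels, pat$md, pat$fa)
  expect_equal(f[["caudal_motor_surface_MD"]] / 0.7e-3, 1.10, tolerance = 0.01)
  expect_equal(f[["limbic_surface_MD"]] / 0.7e-3, 1.00, tolerance = 0.01)
})

test_that("feature table: column combinatorics, hemisphere policies, CSV round trip", {
  w <- toy_world()
  cohort <- generate_cohort(cohort_spec(n = c(HC = 2L, iRBD = 1L), seed = 3))
  meshes <- list(SNc_R = w$mesh,
                 SNc_L = extract_surface(w$atlas$prob$SNc_L, 0.3, 100, 0, "SNc", "L"))
  per <- list()
  for (i in seq_len(nrow(cohort))) {
    sid <- cohort$subject[i]
    maps <- generate_subject_maps(w$atlas, effect_spec(), cohort$group[i],
                                  derive_seed(1, "m", sid))
    streams <- list(); parcs <- list()
    for (nm in names(meshes)) {
      prof <- truth_profile(w$spec, meshes[[nm]], dominant = 0.85)
      streams[[nm]] <- generate_streamlines(meshes[[nm]], w$atlas$cortical_labels,
                                            prof, 15, derive_seed(1, "s", sid, nm))
      C <- count_connections(streams[[nm]], w$atlas$cortical_labels,
                             nrow(meshes[[nm]]$vertices), 4)
      parcs[[nm]] <- assign_subregions(C, 3)
    }
    per[[sid]] <- list(meshes = meshes, parcs = parcs, streams = streams,
                       md = maps$md, fa = maps$fa)
  }
  ft <- build_feature_table(cohort, per, w$atlas$cortical_labels)
  # SNc only: (4 subregions + total) x (bundle|surface) x (MD|FA) = 20 columns
  expect_identical(ncol(ft) - 1L, 20L)
  expect_identical(ft$subject, cohort$subject)
  fts <- build_feature_table(cohort, per, w$atlas$cortical_labels,
                             hemisphere_policy = "separate")
  expect_identical(ncol(fts) - 1L, 40L)
  # averaged value is the vertex-count-weighted mean of the separate values
  wL <- nrow(meshes$SNc_L$vertices); wR <- nrow(meshes$SNc_R$vertices)
  expect_equal(ft$SNc_total_surface_MD,
               (fts$SNc_L_total_surface_MD * wL + fts$SNc_R_total_surface_MD * wR) / (wL + wR))
  # CSV round trip at full precision
  f <- tempfile(fileext = ".csv")
  write_feature_table(ft, f)
  back <- read_feature_table(f)
  for (k in setdiff(names(ft), "subject")) expect_equal(back[[k]], ft[[k]])
  expect_true(file.exists(paste0(f, ".json")))
  # missing modality: row retained with NAs plus a warning
  per2 <- per; per2[[cohort$subject[2]]]$md <- NULL
  expect_warning(ft2 <- build_feature_table(cohort, per2, w$atlas$cortical_labels),
                 "missing a modality")
  expect_true(all(is.na(ft2[2, -1])))
})
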