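test_that("phantom atlas: probabilities in [0,1], blobs interior, labels disjoint, deterministic", {
  w <- toy_world()
  for (p in w$atlas$prob) {
    expect_true(all(p$data >= 0 & p$data <= 1))
  }
  lab <- w$atlas$cortical_labels$data
  expect_true(all(lab %in% 0:6))
  # both hemispheres expose all six targets
  W <- subparc:::phantom_grid_world(w$spec)
  for (h in c(-1, 1)) expect_setequal(unique(lab[W[, 1] * h > 0 & lab > 0]), 1:6)
  # fixed spec -> byte-identical volumes on repeated generation
  again <- generate_atlas(toy_phantom())
  expect_identical(again$prob$SNc_R$data, w$atlas$prob$SNc_R$data)
  expect_identical(again$cortical_labels$data, lab)
  # configuration errors
  expect_error(phantom_spec(grid_shape = c(8, 24, 24)), class = "subparc_config_error")
  expect_error(phantom_spec(structures = list(striatum = list(centre = c(10, 0, 0), radius_mm = 8))),
               "overflows", class = "subparc_config_error")
})

test_that("degenerate blob of radius 0 yields a probability map with at most one voxel", {
  sp <- phantom_spec(grid_shape = c(24, 24, 24),
                     structures = list(SNc = list(centre = c(2.5, 0.5, 0.5), radius_mm = 0)))
  at <- generate_atlas(sp)
  expect_lte(sum(at$prob$SNc_R$data > 0), 1)
})

test_that("thresholded blob voxel count equals brute-force enumeration of voxel centres", {
  sp <- phantom_spec(grid_shape = c(24, 24, 24),
                     structures = list(SNc = list(centre = c(4, -2, 1), radius_mm = 5)))
  at <- generate_atlas(sp)
  got <- sum(at$prob$SNc_R$data > 0.5)
  W <- subparc:::phantom_grid_world(sp)
  brute <- sum(sqrt(colSums((t(W) - c(4, -2, 1))^2)) < 5)
  expect_identical(got, brute)
})

test_that("streamline generation: conservation, deterministic profiles, seeded reproducibility", {
  w <- toy_world()
  V <- nrow(w$mesh$vertices)
  # delta profile on target 4: every streamline terminates in label 4
  prof <- matrix(0, 1, 5); prof[4] <- 1
  st <- generate_streamlines(w$mesh, w$atlas$cortical_labels, prof,
                             n_seeds_per_vertex = 10, seed = 2, targets = 4)
  expect_identical(n_streamlines(st), V * 10L)
  tl <- terminal_label(st, w$atlas$cortical_labels)
  expect_true(all(tl == 4L))
  C <- count_connections(st, w$atlas$cortical_labels, V, 6)
  expect_true(all(C[, 4] == 10L))
  expect_true(all(C[, -4] == 0L))
  # 100% failure: all terminal labels 0
  pf <- matrix(c(0, 0, 0, 0, 1), 1)
  stf <- generate_streamlines(w$mesh, w$atlas$cortical_labels, pf, 5, seed = 2)
  expect_true(all(terminal_label(stf, w$atlas$cortical_labels) == 0L))
  # same seed -> bit-identical; different seed -> different
  st2 <- generate_streamlines(w$mesh, w$atlas$cortical_labels, prof, 10, seed = 2)
  expect_identical(st$coords, st2$coords)
  st3 <- generate_streamlines(w$mesh, w$atlas$cortical_labels, prof, 10, seed = 3)
  expect_false(identical(st$coords, st3$coords))
  # vertex outside the grid is a geometry error
  bad <- w$mesh; bad$vertices[1, ] <- c(999, 0, 0)
  expect_error(generate_streamlines(bad, w$atlas$cortical_labels, prof, 2, seed = 1),
               class = "subparc_data_error")
})

test_that("per-vertex termination counts follow the drawn binomial profile", {
  w <- toy_world()
  prof <- c(0.7, 0.3, 0, 0, 0)  # 70% limbic, 30% executive
  st <- generate_streamlines(w$mesh, w$atlas$cortical_labels, matrix(prof, 1), 250, seed = 8)
  C <- count_connections(st, w$atlas$cortical_labels, nrow(w$mesh$vertices), 6)
  expect_equal(mean(C[, 1]), 175, tolerance = 0.02)
  env <- qbinom(c(0.005, 0.995), 250, 0.7)
  inside <- mean(C[, 1] >= env[1] & C[, 1] <= env[2])
  expect_gte(inside, 0.97)   # 99% envelope; allow Monte-Carlo slack
  expect_true(all(C[, 1] + C[, 2] == 250L))
})

test_that("subject maps: noise-free algebra and clipping", {
  w <- toy_world()
  eff0 <- effect_spec(shift = 0, subject_sd = 0, voxel_sd = 0)
  a <- generate_subject_maps(w$atlas, eff0, "iRBD", 5)
  b <- generate_subject_maps(w$atlas, eff0, "HC", 6)
  expect_identical(a$md$data, b$md$data)   # no effect, no noise -> identical maps
  eff <- effect_spec(shift = 0.10, subject_sd = 0, voxel_sd = 0)
  p <- generate_subject_maps(w$atlas, eff, "iRBD", 5)
  h <- generate_subject_maps(w$atlas, eff, "HC", 5)
  mask <- subparc:::truth_voxel_mask(w$atlas, "SNc", "R", 4L)
  expect_equal(mean(p$md$data[mask]) / mean(h$md$data[mask]), 1.10, tolerance = 1e-12)
  expect_identical(h$md$data, a$md$data)   # HC unaffected
  # negative MD from extreme noise is clipped with a warning
  effn <- effect_spec(shift = 0, subject_sd = 0, voxel_sd = 1.5)
  expect_warning(res <- generate_subject_maps(w$atlas, effn, "HC", 11), "clipped")
  expect_gte(res$n_clipped, 1)
  expect_true(all(res$md$data >= 0) && all(res$fa$data >= 0 & res$fa$data <= 1))
})

test_that("Monte-Carlo group mean difference matches the injected shift", {
  w <- toy_world()
  eff <- effect_spec(shift = 0.05, subject_sd = 0.02, voxel_sd = 0)
  mask <- subparc:::truth_voxel_mask(w$atlas, "SNc", "R", 4L)
  n <- 200
  logm <- function(grp, off) vapply(seq_len(n), function(i) {
    log(mean(generate_subject_maps(w$atlas, eff, grp, derive_seed(1, grp, i + off))$md$data[mask]))
  }, 0)
  d <- mean(logm("iRBD", 0)) - mean(logm("HC", 1e5))
  se <- 0.02 * sqrt(2 / n)
  expect_lt(abs(d - log(1.05)), 3 * se)
})

test_that("cohort generation: sizes, reproducibility, extensibility, null clinical correlation", {
  cs <- cohort_spec(n = c(HC = 5L, iRBD = 5L, ePD = 5L), seed = 4)
  coh <- generate_cohort(cs)
  expect_identical(nrow(coh), 15L)
  expect_identical(generate_cohort(cs), coh)
  # enlarging one group never perturbs existing subjects
  big <- generate_cohort(cohort_spec(n = c(HC = 5L, iRBD = 9L, ePD = 5L), seed = 4))
  expect_identical(big[match(coh$subject, big$subject), names(coh)],
                   coh, ignore_attr = TRUE)
  expect_error(cohort_spec(n = c(HC = 0L, iRBD = 5L, ePD = 5L)), class = "subparc_config_error")
  # single-site cohort composition
  west <- generate_cohort(cohort_spec())
  expect_identical(unname(table(west$group)[c("HC", "iRBD", "ePD")]),
                   table(factor(c(rep("a", 45), rep("b", 19), rep("c", 26))), dnn = NULL)[1:3],
               ignore_attr = TRUE)
  # configured rho = 0: sample Spearman within the null 95% band
  pat <- west[west$group != "HC", ]
  r <- spearman_assoc(pat$updrs3, pat$subject_intercept)
  expect_gt(r$p, 0.025)
  # configured rho = 0.5 shows up
  c2 <- generate_cohort(cohort_spec(updrs_effect_rho = 0.5, seed = 9))
  p2 <- c2[c2$group != "HC", ]
  expect_gt(spearman_assoc(p2$updrs3, p2$subject_intercept)$r_s, 0.25)
})

test_that("feature grid has the canonical 68 columns and the simulator honours effects", {
  g <- feature_grid()
  expect_identical(nrow(g), 68L)   # 17 region slots x bundle/surface x MD/FA
  coh <- generate_cohort(cohort_spec(n = c(HC = 20L, iRBD = 10L, ePD = 10L), seed = 2))
  eff <- effect_spec(shift = 0.10, subject_sd = 0, voxel_sd = 0)
  ft <- simulate_feature_table(coh, eff, seed = 3, feature_sd = 0)
  target <- "SNc_caudal_motor_surface_MD"
  ratio <- mean(ft[[target]][coh$group != "HC"]) / mean(ft[[target]][coh$group == "HC"])
  agefac <- mean(1 + 0.01 * (coh$age[coh$group != "HC"] - 65) / 10) /
            mean(1 + 0.01 * (coh$age[coh$group == "HC"] - 65) / 10)
  expect_equal(ratio / agefac, 1.10, tolerance = 1e-6)
  # untouched features carry no group shift beyond the age trend
  other <- "SNc_caudal_motor_bundle_MD"   # surface-domain effect only
  r2 <- mean(ft[[other]][coh$group != "HC"]) / mean(ft[[other]][coh$group == "HC"])
  expect_equal(r2 / agefac, 1.0, tolerance = 1e-6)
})

test_that("fixture study materialises a complete BIDS-like toy directory", {
  dir <- tempfile("toystudy")
  write_fixture_study(dir, phantom = toy_phantom(),
                      cohort_spec_ = cohort_spec(n = c(HC = 2L, iRBD = 2L, ePD = 2L)),
                      n_seeds_per_vertex = 5L, structures = "SNc")
  expect_true(file.exists(file.path(dir, "participants.csv")))
  expect_true(file.exists(file.path(dir, "atlas", "cortical_labels.nii.gz")))
  coh <- utils::read.csv(file.path(dir, "participants.csv"))
  sid <- coh$subject[1]
  expect_true(file.exists(file.path(dir, sid, "dwi", paste0(sid, "_MD.nii.gz"))))
  expect_true(file.exists(file.path(dir, sid, "dwi", paste0(sid, "_SNc_L.tck"))))
})
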