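# Synthetic phantom / cohort generator. Everything downstream is tested
# against data produced here with known ground truth: smooth probability
# blobs standing in for a probabilistic subcortical atlas, six cortical
# target patches per hemisphere, geometric streamlines seeded at mesh
# vertices, MD/FA scalar fields with lognormal subject intercepts and voxel
# noise, injectable subregion-specific group shifts, and cohort covariates.

#' Canonical cortical target names
#'
#' Targets 1..6 = limbic, executive, rostral-motor, caudal-motor, parietal,
#' occipital. VTA and SNc are parcellated against the first four only; the
#' striatum against all six.
#' @export
CORTICAL_TARGETS <- c("limbic", "executive", "rostral_motor", "caudal_motor",
                      "parietal", "occipital")

#' Targets used for a given structure
#' @param structure "VTA", "SNc" or "striatum".
#' @return character vector of target names (in canonical order).
#' @export
structure_targets <- function(structure) {
  if (structure %in% c("VTA", "SNc")) CORTICAL_TARGETS[1:4]
  else if (structure == "striatum") CORTICAL_TARGETS
  else abort_config(sprintf("unknown structure '%s'", structure))
}

#' Phantom specification
#'
#' Defines the synthetic world: grid geometry, one smooth probability blob
#' per structure and hemisphere, and six disjoint cortical target patches per
#' hemisphere. The blob probability is `exp(-log(2) * (d/r)^2)` so the 0.5
#' isocontour sits exactly at the stated radius.
#'
#' @param grid_shape integer length-3 (>= 16 per axis).
#' @param voxel_size_mm isotropic voxel size.
#' @param structures named list of `list(centre = c(x,y,z) right-hemisphere
#'   world mm, radius_mm =)`; the left hemisphere is mirrored in x.
#' @param seed master seed (stored; the atlas itself is deterministic).
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(32L, 32L, 32L), voxel_size_mm = 1,
                         structures = list(
                           striatum = list(centre = c(7, 2, 2), radius_mm = 6),
                           SNc      = list(centre = c(5.5, -4, -5), radius_mm = 3.5),
                           VTA      = list(centre = c(2, -5, -5), radius_mm = 2.2)),
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (any(grid_shape < 16L)) abort_config("phantom_spec: grid_shape must be >= 16 per axis")
  ext <- voxel_size_mm * (grid_shape - 1) / 2   # half field of view, grid centred on 0
  for (nm in names(structures)) {
    st <- structures[[nm]]
    if (st$radius_mm < 0) abort_config("phantom_spec: negative blob radius")
    if (any(abs(st$centre) + st$radius_mm >= ext - voxel_size_mm))
      abort_config(sprintf("phantom_spec: %s blob overflows the grid", nm))
  }
  structure(list(grid_shape = grid_shape, voxel_size_mm = voxel_size_mm,
                 structures = structures, seed = as.integer(seed)),
            class = "phantom_spec")
}

phantom_affine <- function(spec) {
  aff <- diag(4)
  diag(aff)[1:3] <- spec$voxel_size_mm
  aff[1:3, 4] <- -spec$voxel_size_mm * (spec$grid_shape - 1) / 2
  aff
}

# world coordinates of every voxel centre, nvox x 3 (column-major order)
phantom_grid_world <- function(spec) {
  d <- spec$grid_shape
  idx <- as.matrix(expand.grid(i = 0:(d[1] - 1), j = 0:(d[2] - 1), k = 0:(d[3] - 1)))
  aff <- phantom_affine(spec)
  t(aff[1:3, 1:3] %*% t(idx) + aff[1:3, 4])
}

#' Generate the phantom atlas
#'
#' @param spec a [phantom_spec()].
#' @return list with `prob` (named list of probability [scalar_volume()]s,
#'   names like "SNc_L"), `cortical_labels` (integer label volume, labels 1-6
#'   per hemisphere, 0 background), and `spec`.
#' @export
generate_atlas <- function(spec) {
  d <- spec$grid_shape
  aff <- phantom_affine(spec)
  W <- phantom_grid_world(spec)
  prob <- list()
  for (nm in names(spec$structures)) {
    st <- spec$structures[[nm]]
    for (hemi in c("L", "R")) {
      ctr <- st$centre
      if (hemi == "L") ctr[1] <- -ctr[1]
      dist <- sqrt(colSums((t(W) - ctr)^2))
      p <- if (st$radius_mm == 0) as.numeric(dist == 0)
           else exp(-log(2) * (dist / st$radius_mm)^2)
      p[p < 1e-6] <- 0
      prob[[paste(nm, hemi, sep = "_")]] <- scalar_volume(array(p, d), aff, "prob")
    }
  }
  lab <- integer(prod(d))
  # six disjoint patches per hemisphere: a 3-voxel-thick slab at the top of
  # the grid, split by hemisphere (x sign) and into six y bands
  kz <- W[, 3] >= max(W[, 3]) - 3 * spec$voxel_size_mm + 1e-9
  ylo <- min(W[, 2]); yhi <- max(W[, 2])
  band <- pmin(6L, 1L + as.integer(floor((W[, 2] - ylo) / ((yhi - ylo) / 6 + 1e-12))))
  lab[kz] <- band[kz]
  labvol <- scalar_volume(array(as.double(lab), d), aff, "label")
  ov <- check_patches_disjoint(labvol)
  if (!ov) abort_config("generate_atlas: overlapping cortical patches")
  list(prob = prob, cortical_labels = labvol, spec = spec)
}

check_patches_disjoint <- function(labvol) {
  all(labvol$data == round(labvol$data)) && all(labvol$data >= 0)
}

# hemisphere of world points under the phantom convention: x < 0 -> L
point_hemisphere <- function(pts) ifelse(rbind_pts(pts)[, 1] < 0, "L", "R")

#' Ground-truth subregion of world points
#'
#' The phantom's generating rule: a structure blob is divided into
#' equal-width y bands (4 for VTA/SNc, 6 for the striatum) spanning
#' `centre_y +/- radius`; each band maps to one cortical target in canonical
#' order. Used both to paint voxel-level effects and to define the truth
#' vertex parcellation.
#'
#' @param spec a [phantom_spec()].
#' @param structure structure name.
#' @param pts n x 3 world-mm points.
#' @return integer target ids (1-based, canonical order), clamped to range.
#' @export
truth_subregion <- function(spec, structure, pts) {
  st <- spec$structures[[structure]]
  if (is.null(st)) abort_config(sprintf("unknown structure '%s'", structure))
  pts <- rbind_pts(pts)
  nt <- length(structure_targets(structure))
  y <- pts[, 2] - st$centre[2]
  band <- 1L + as.integer(floor((y + st$radius_mm) / (2 * st$radius_mm / nt)))
  pmin(pmax(band, 1L), nt)
}

# voxel mask (logical array) of the "true" subregion of a structure: blob
# probability >= paint_threshold AND y inside the subregion's band extended
# by band_margin_mm (default one voxel) so surface vertices of the band
# sample fully-painted trilinear neighbourhoods (exact closed loop)
truth_voxel_mask <- function(atlas, structure, hemisphere, subregion,
                             paint_threshold = 0.15, band_margin_mm = NULL) {
  spec <- atlas$spec
  if (is.null(band_margin_mm)) band_margin_mm <- spec$voxel_size_mm
  st <- spec$structures[[structure]]
  p <- atlas$prob[[paste(structure, hemisphere, sep = "_")]]
  W <- phantom_grid_world(spec)
  nt <- length(structure_targets(structure))
  w <- 2 * st$radius_mm / nt
  ylo <- st$centre[2] - st$radius_mm + (subregion - 1) * w
  yhi <- ylo + w
  if (subregion == 1L) ylo <- -Inf      # edge bands absorb the blob poles,
  if (subregion == nt) yhi <- Inf       # matching the clamped vertex banding
  inband <- W[, 2] >= ylo - band_margin_mm & W[, 2] < yhi + band_margin_mm
  array(p$data >= paint_threshold & inband, spec$grid_shape)
}

#' Injected group-effect specification
#'
#' @param structure,subregion which truth subregion carries the effect
#'   (subregion is a 1-based canonical target id).
#' @param metric "MD" or "FA" (which scalar map is shifted).
#' @param domain feature kind the effect targets: "surface" (default),
#'   "bundle", or "both". The feature-level simulator applies the shift to
#'   exactly this kind; the image-level generator shifts the map itself, so a
#'   surface effect leaks marginally (about 1 %) into the matching bundle
#'   mean — the partial-volume analogue.
#' @param groups character vector of affected groups.
#' @param shift multiplicative shift (0.05 = +5 %); must be > -1.
#' @param subject_sd between-subject SD of the lognormal intercept.
#' @param voxel_sd within-map multiplicative voxel noise SD.
#' @return an object of class `effect_spec`.
#' @export
effect_spec <- function(structure = "SNc", subregion = 4L, metric = "MD",
                        domain = c("surface", "bundle", "both"),
                        groups = c("iRBD", "ePD"), shift = 0.05,
                        subject_sd = 0.03, voxel_sd = 0.01) {
  if (shift <= -1) abort_config("effect_spec: shift must be > -100%")
  if (subject_sd < 0 || voxel_sd < 0) abort_config("effect_spec: noise SDs must be >= 0")
  if (!metric %in% c("MD", "FA")) abort_config("effect_spec: metric must be MD or FA")
  structure(list(structure = structure, subregion = as.integer(subregion),
                 metric = metric, domain = match.arg(domain), groups = groups,
                 shift = shift, subject_sd = subject_sd, voxel_sd = voxel_sd),
            class = "effect_spec")
}

#' Generate per-subject MD and FA maps
#'
#' Baseline grey-matter MD (default 0.7e-3 mm^2/s) and FA (default 0.25)
#' everywhere; the effect's truth subregion voxels (in both hemispheres) are
#' shifted multiplicatively for affected groups; a lognormal subject
#' intercept and multiplicative Gaussian voxel noise are applied. MD is
#' clipped at 0 and FA to [0, 1]; clip counts are returned.
#'
#' @param atlas output of [generate_atlas()].
#' @param effect an [effect_spec()] (or NULL for a pure-null subject).
#' @param group this subject's group label.
#' @param subject_seed integer seed for this subject's stream.
#' @param md_baseline,fa_baseline baseline values.
#' @param subject_factor optional externally-drawn lognormal intercept
#'   (overrides the internally drawn one; lets the cohort's latent intercept
#'   drive the maps).
#' @return list(md =, fa =, n_clipped =, subject_factor =).
#' @export
generate_subject_maps <- function(atlas, effect, group, subject_seed,
                                  md_baseline = 0.7e-3, fa_baseline = 0.25,
                                  subject_factor = NULL) {
  spec <- atlas$spec
  d <- spec$grid_shape
  aff <- phantom_affine(spec)
  subject_sd <- if (is.null(effect)) 0 else effect$subject_sd
  voxel_sd <- if (is.null(effect)) 0 else effect$voxel_sd
  with_seed(subject_seed, {
    if (is.null(subject_factor))
      subject_factor <- exp(rnorm(1, 0, subject_sd))
    md <- array(md_baseline, d)
    fa <- array(fa_baseline, d)
    if (!is.null(effect) && effect$shift != 0 && group %in% effect$groups) {
      mask <- truth_voxel_mask(atlas, effect$structure, "L", effect$subregion) |
              truth_voxel_mask(atlas, effect$structure, "R", effect$subregion)
      if (effect$metric == "MD") md[mask] <- md[mask] * (1 + effect$shift)
      else fa[mask] <- fa[mask] * (1 + effect$shift)
    }
    md <- md * subject_factor
    fa <- fa * subject_factor
    if (voxel_sd > 0) {
      md <- md * (1 + rnorm(length(md), 0, voxel_sd))
      fa <- fa * (1 + rnorm(length(fa), 0, voxel_sd))
    }
    n_clipped <- sum(md < 0) + sum(fa < 0) + sum(fa > 1)
    if (n_clipped > 0) warning(sprintf("generate_subject_maps: %d voxels clipped", n_clipped))
    md[md < 0] <- 0
    fa[fa < 0] <- 0; fa[fa > 1] <- 1
    list(md = scalar_volume(md, aff, "MD"),
         fa = scalar_volume(fa, aff, "FA"),
         n_clipped = n_clipped, subject_factor = subject_factor)
  })
}

#' Generate geometric streamlines from a seeded surface
#'
#' Stands in for probabilistic tractography: for each mesh vertex,
#' `n_seeds_per_vertex` streamlines are drawn; each picks a cortical target
#' (or failure) from the vertex's row of `profile`, then runs as a slightly
#' bowed 3-point polyline from the vertex to a random point inside a voxel of
#' that target patch in the vertex's hemisphere. Failed seeds terminate in a
#' background (label 0) voxel.
#'
#' @param mesh a [surface_mesh()].
#' @param cortical_labels label [scalar_volume()].
#' @param profile V x (T+1) matrix; columns = targets 1..T then "fail"; rows
#'   sum to 1. A single row is recycled to all vertices.
#' @param n_seeds_per_vertex seeds per vertex (>= 1; the tractography recipe
#'   uses 250).
#' @param seed RNG seed.
#' @param targets number of targets T (defaults from the structure tag).
#' @return a [streamline_set()] with `seed_vertex` set and the drawn target
#'   stored in `$drawn_target` (0 = fail).
#' @export
generate_streamlines <- function(mesh, cortical_labels, profile,
                                 n_seeds_per_vertex = 250L, seed = 1L,
                                 targets = NULL) {
  V <- nrow(mesh$vertices)
  if (n_seeds_per_vertex < 1) abort_config("generate_streamlines: n_seeds_per_vertex must be >= 1")
  if (is.null(dim(profile))) profile <- matrix(profile, nrow = 1)
  if (nrow(profile) == 1L) profile <- profile[rep(1L, V), , drop = FALSE]
  if (nrow(profile) != V) abort_config("generate_streamlines: profile rows must match vertex count")
  if (max(abs(rowSums(profile) - 1)) > 1e-8)
    abort_config("generate_streamlines: profile rows must sum to 1")
  Tn <- ncol(profile) - 1L
  d <- dim(cortical_labels$data)
  vvox <- world_to_voxel(cortical_labels, mesh$vertices)
  if (any(vvox < -0.5) || any(sweep(vvox, 2, d - 0.5, `>`)))
    abort_data("generate_streamlines: vertex outside grid bounds")
  # candidate voxels per (target, hemisphere); hemisphere by world x sign
  W <- voxel_to_world(cortical_labels,
                      as.matrix(expand.grid(i = 0:(d[1] - 1), j = 0:(d[2] - 1),
                                            k = 0:(d[3] - 1))))
  labv <- as.vector(cortical_labels$data)
  hemi_all <- point_hemisphere(W)
  cand <- list()
  for (t in seq_len(Tn)) for (h in c("L", "R"))
    cand[[paste(t, h)]] <- which(labv == t & hemi_all == h)
  bg <- which(labv == 0)
  vhemi <- point_hemisphere(mesh$vertices)
  vs <- voxel_size(cortical_labels)
  with_seed(seed, {
    n_total <- V * n_seeds_per_vertex
    coords <- matrix(0, 3L * n_total, 3)
    drawn <- integer(n_total)
    at <- 0L
    for (v in seq_len(V)) {
      tgt <- sample.int(Tn + 1L, n_seeds_per_vertex, replace = TRUE, prob = profile[v, ])
      tgt[tgt == Tn + 1L] <- 0L   # fail
      endvox <- integer(n_seeds_per_vertex)
      for (t in unique(tgt)) {
        sel <- tgt == t
        pool <- if (t == 0L) bg else cand[[paste(t, vhemi[v])]]
        if (!length(pool)) abort_data(sprintf("generate_streamlines: no voxels with label %d in hemisphere %s", t, vhemi[v]))
        endvox[sel] <- pool[sample.int(length(pool), sum(sel), replace = TRUE)]
      }
      ep <- W[endvox, , drop = FALSE] +
        matrix(runif(3 * n_seeds_per_vertex, -0.45, 0.45), ncol = 3) *
        matrix(vs, n_seeds_per_vertex, 3, byrow = TRUE)
      sp <- matrix(mesh$vertices[v, ], n_seeds_per_vertex, 3, byrow = TRUE)
      mid <- (sp + ep) / 2
      dir <- ep - sp
      # bow the midpoint perpendicular to the chord (makes bundles non-straight)
      perp <- cbind(-dir[, 2], dir[, 1], 0)
      pl <- sqrt(rowSums(perp^2)); pl[pl == 0] <- 1
      bow <- 0.15 * sqrt(rowSums(dir^2)) * runif(n_seeds_per_vertex, -1, 1)
      mid <- mid + (perp / pl) * bow
      rows <- at + seq_len(3L * n_seeds_per_vertex)
      block <- matrix(0, 3L * n_seeds_per_vertex, 3)
      block[seq(1, by = 3, length.out = n_seeds_per_vertex), ] <- sp
      block[seq(2, by = 3, length.out = n_seeds_per_vertex), ] <- mid
      block[seq(3, by = 3, length.out = n_seeds_per_vertex), ] <- ep
      coords[rows, ] <- block
      drawn[(v - 1L) * n_seeds_per_vertex + seq_len(n_seeds_per_vertex)] <- tgt
      at <- at + 3L * n_seeds_per_vertex
    }
    out <- streamline_set(coords, rep(3L, n_total),
                          seed_vertex = rep(seq_len(V), each = n_seeds_per_vertex))
    out$drawn_target <- drawn
    out
  })
}

#' Cohort specification
#'
#' Group compositions default to the single-site cohort of the study design
#' this package emulates: 45 healthy controls (HC), 19 iRBD, 26 ePD.
#' Covariate distributions are configurable per group; `updrs_effect_rho`
#' sets a Gaussian-copula Spearman correlation between the motor score and
#' the subject's latent microstructure intercept.
#'
#' @param n named integer vector of group sizes (names HC/iRBD/ePD).
#' @param seed master seed.
#' @param sites character vector of site labels to draw from.
#' @param age_mean,age_sd,moca_mean,moca_sd,updrs_mean,updrs_sd,rbdsq_mean,rbdsq_sd
#'   named-per-group (or scalar) distribution parameters.
#' @param male_prob per-group probability of male sex.
#' @param updrs_effect_rho target Spearman correlation between MDS-UPDRS-III
#'   and the latent subject intercept (patients only).
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n = c(HC = 45L, iRBD = 19L, ePD = 26L), seed = 1L,
                        sites = "Western",
                        age_mean = c(HC = 66, iRBD = 67, ePD = 66), age_sd = 7,
                        male_prob = c(HC = 0.5, iRBD = 0.8, ePD = 0.65),
                        moca_mean = c(HC = 27.5, iRBD = 26.5, ePD = 26.8), moca_sd = 2,
                        updrs_mean = c(HC = 2, iRBD = 5, ePD = 20), updrs_sd = c(HC = 2, iRBD = 4, ePD = 8),
                        rbdsq_mean = c(HC = 2, iRBD = 9, ePD = 4), rbdsq_sd = 2,
                        updrs_effect_rho = 0) {
  if (any(n < 1)) abort_config("cohort_spec: every group needs n >= 1")
  structure(list(n = n, seed = as.integer(seed), sites = sites,
                 age_mean = age_mean, age_sd = age_sd, male_prob = male_prob,
                 moca_mean = moca_mean, moca_sd = moca_sd,
                 updrs_mean = updrs_mean, updrs_sd = updrs_sd,
                 rbdsq_mean = rbdsq_mean, rbdsq_sd = rbdsq_sd,
                 updrs_effect_rho = updrs_effect_rho),
            class = "cohort_spec")
}

per_group <- function(x, g) if (length(x) == 1L) unname(x) else unname(x[[g]])

#' Generate a cohort table
#'
#' One row per subject; each subject's covariates are drawn from an
#' independent stream derived from `(seed, subject id)`, so enlarging a group
#' never perturbs existing subjects. `subject_intercept` is the latent
#' standard-normal driving the subject's microstructure intercept (correlated
#' with MDS-UPDRS-III via `updrs_effect_rho`).
#'
#' @param spec a [cohort_spec()].
#' @return a data.frame (class `cohort_table`).
#' @export
generate_cohort <- function(spec) {
  rho_s <- spec$updrs_effect_rho
  rho <- 2 * sin(pi * rho_s / 6)   # Gaussian-copula Pearson rho for target Spearman rho
  rows <- list()
  for (g in names(spec$n)) {
    for (i in seq_len(spec$n[[g]])) {
      sid <- sprintf("sub-%s-%03d", g, i)
      s <- derive_seed(spec$seed, "subject", sid)
      rows[[sid]] <- with_seed(s, {
        z1 <- rnorm(1); z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(1)
        updrs <- max(0, round(per_group(spec$updrs_mean, g) + per_group(spec$updrs_sd, g) * z1))
        data.frame(
          subject = sid, group = g,
          age = round(per_group(spec$age_mean, g) + per_group(spec$age_sd, g) * rnorm(1), 1),
          sex = if (runif(1) < per_group(spec$male_prob, g)) "M" else "F",
          site = spec$sites[1 + (sum(utf8ToInt(sid)) %% length(spec$sites))],
          moca = min(30, max(0, round(per_group(spec$moca_mean, g) + per_group(spec$moca_sd, g) * rnorm(1)))),
          updrs3 = updrs,
          rbdsq = max(0, round(per_group(spec$rbdsq_mean, g) + per_group(spec$rbdsq_sd, g) * rnorm(1))),
          duration = if (g == "ePD") round(abs(rnorm(1, 1.7, 0.8)), 1) else NA_real_,
          subject_intercept = z2,
          stringsAsFactors = FALSE)
      })
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("cohort_table", "data.frame")
  out
}

# --- feature-level fast simulator -------------------------------------------

#' The canonical feature grid
#'
#' All (structure, subregion-or-total, bundle|surface, MD|FA) combinations:
#' striatum has six subregions, VTA and SNc four, plus a "total" slot each —
#' 17 region slots x 4 metrics = 68 feature columns. The "total" bundle is
#' the union of the subregion bundles.
#'
#' @return data.frame with columns structure, subregion, domain, metric, name.
#' @export
feature_grid <- function() {
  rows <- list()
  for (st in c("VTA", "SNc", "striatum")) {
    subs <- c("total", structure_targets(st))
    for (sub in subs) for (dom in c("bundle", "surface")) for (met in c("MD", "FA")) {
      rows[[length(rows) + 1L]] <- data.frame(
        structure = st, subregion = sub, domain = dom, metric = met,
        name = paste(st, sub, dom, met, sep = "_"), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Simulate a feature table directly from the generative model
#'
#' The fast path used by the type-I calibration and power suites: draws each
#' subject's feature vector from the same model the imaging pipeline induces
#' (baseline x lognormal subject intercept x lognormal feature noise, with an
#' age trend and the injected multiplicative group shift on the affected
#' feature), without synthesising images. The closed-loop identity between
#' this model and the full pipeline at zero noise is tested separately.
#'
#' @param cohort a [generate_cohort()] table.
#' @param effect an [effect_spec()] or NULL (null world).
#' @param seed RNG seed for the feature-level measurement noise.
#' @param md_baseline,fa_baseline baselines.
#' @param feature_sd per-feature lognormal measurement noise SD.
#' @param age_slope_per_decade multiplicative MD increase per decade of age.
#' @return data.frame: subject column + one numeric column per feature.
#' @export
simulate_feature_table <- function(cohort, effect = NULL, seed = 1L,
                                   md_baseline = 0.7e-3, fa_baseline = 0.25,
                                   feature_sd = 0.01, age_slope_per_decade = 0.01) {
  grid <- feature_grid()
  n <- nrow(cohort)
  subject_sd <- if (is.null(effect)) 0.03 else effect$subject_sd
  intercept <- exp(subject_sd * cohort$subject_intercept)
  agefac <- 1 + age_slope_per_decade * (cohort$age - 65) / 10
  with_seed(seed, {
    M <- matrix(0, n, nrow(grid))
    for (j in seq_len(nrow(grid))) {
      base <- if (grid$metric[j] == "MD") md_baseline else fa_baseline
      shift <- rep(1, n)
      if (!is.null(effect) && effect$shift != 0 &&
          grid$structure[j] == effect$structure &&
          grid$metric[j] == effect$metric &&
          (effect$domain == "both" || grid$domain[j] == effect$domain) &&
          grid$subregion[j] == structure_targets(effect$structure)[effect$subregion]) {
        shift[cohort$group %in% effect$groups] <- 1 + effect$shift
      }
      M[, j] <- base * shift * intercept * agefac * exp(rnorm(n, 0, feature_sd))
    }
    colnames(M) <- grid$name
    cbind(data.frame(subject = cohort$subject, stringsAsFactors = FALSE),
          as.data.frame(M))
  })
}

#' Materialise a toy study directory
#'
#' Writes a complete BIDS-like synthetic study: the phantom atlas
#' (probability and label NIfTIs), per-subject MD/FA volumes and a TCK
#' streamline file per structure, and the cohort CSV.
#'
#' @param dir output directory (created).
#' @param phantom a [phantom_spec()].
#' @param cohort_spec_ a [cohort_spec()].
#' @param effect an [effect_spec()] or NULL.
#' @param n_seeds_per_vertex seeds per vertex for the toy streamlines.
#' @param structures which structures to simulate streamlines for.
#' @param mesh_params per-structure mesh recipe (threshold, upsample_pct,
#'   decimate_fraction); defaults to the atlas recipe. Use the same values in
#'   the pipeline config that consumes the study.
#' @return the directory path, invisibly.
#' @export
write_fixture_study <- function(dir, phantom = phantom_spec(),
                                cohort_spec_ = cohort_spec(n = c(HC = 4L, iRBD = 4L, ePD = 4L)),
                                effect = effect_spec(), n_seeds_per_vertex = 25L,
                                structures = "SNc", mesh_params = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  atlas <- generate_atlas(phantom)
  adir <- file.path(dir, "atlas")
  dir.create(adir, showWarnings = FALSE)
  for (nm in names(atlas$prob)) write_nifti(atlas$prob[[nm]], file.path(adir, paste0(nm, "_prob.nii.gz")))
  write_nifti(atlas$cortical_labels, file.path(adir, "cortical_labels.nii.gz"))
  cohort <- generate_cohort(cohort_spec_)
  write.csv(cohort, file.path(dir, "participants.csv"), row.names = FALSE)
  meshes <- list()
  for (st in structures) for (h in c("L", "R")) {
    mp <- mesh_params[[st]] %||%
      list(threshold = if (st == "striatum") 0.5 else 0.3,
           upsample_pct = if (st == "striatum") 100 else 200,
           decimate_fraction = if (st == "striatum") 0.25 else 0)
    m <- extract_surface(atlas$prob[[paste(st, h, sep = "_")]],
                         threshold = mp$threshold,
                         upsample_pct = mp$upsample_pct,
                         decimate_fraction = mp$decimate_fraction,
                         structure = st, hemisphere = h)
    meshes[[paste(st, h, sep = "_")]] <- m
    write_ply(m, file.path(adir, paste0(st, "_", h, ".ply")))
  }
  for (i in seq_len(nrow(cohort))) {
    sid <- cohort$subject[i]
    sdir <- file.path(dir, sid, "dwi")
    dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
    maps <- generate_subject_maps(atlas, effect, cohort$group[i],
                                  derive_seed(phantom$seed, "maps", sid),
                                  subject_factor = exp((effect$subject_sd %||% 0) * cohort$subject_intercept[i]))
    write_nifti(maps$md, file.path(sdir, paste0(sid, "_MD.nii.gz")))
    write_nifti(maps$fa, file.path(sdir, paste0(sid, "_FA.nii.gz")))
    for (nm in names(meshes)) {
      m <- meshes[[nm]]
      prof <- truth_profile(phantom, m, dominant = 0.85)
      str_ <- generate_streamlines(m, atlas$cortical_labels, prof, n_seeds_per_vertex,
                                   seed = derive_seed(phantom$seed, "streams", sid, nm))
      write_tck(str_, file.path(sdir, paste0(sid, "_", nm, ".tck")))
      write.csv(data.frame(seed_vertex = str_$seed_vertex),
                file.path(sdir, paste0(sid, "_", nm, "_seeds.csv")), row.names = FALSE)
    }
  }
  invisible(dir)
}

#' Per-vertex target profile implied by the phantom's ground truth
#'
#' Each vertex sends `dominant` of its streamlines to its truth target; the
#' remainder is split evenly over the other targets and a failure slot.
#'
#' @param spec a [phantom_spec()].
#' @param mesh a [surface_mesh()] (structure tag must be set).
#' @param dominant probability of the truth target (>= 1/T).
#' @param fail_prob probability of failure (background termination).
#' @return V x (T+1) profile matrix.
#' @export
truth_profile <- function(spec, mesh, dominant = 0.85, fail_prob = 0.05) {
  tg <- structure_targets(mesh$structure)
  Tn <- length(tg)
  pts <- mesh$vertices
  pts[, 1] <- abs(pts[, 1])  # mirror L to R for the banding rule
  tv <- truth_subregion(spec, mesh$structure, pts)
  rest <- (1 - dominant - fail_prob) / (Tn - 1)
  prof <- matrix(rest, nrow(pts), Tn + 1L)
  prof[, Tn + 1L] <- fail_prob
  prof[cbind(seq_len(nrow(pts)), tv)] <- dominant
  prof
}
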