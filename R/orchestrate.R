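# End-to-end pipeline runner: turns a study directory (real layout or the
# synthetic toy study) into a feature table, a battery report, and
# classifier reports, with content-keyed stage caching and a JSON-lines log.

MESH_DEFAULTS <- list(
  striatum = list(threshold = 0.5, upsample_pct = 100, decimate_fraction = 0.25),
  SNc      = list(threshold = 0.3, upsample_pct = 200, decimate_fraction = 0),
  VTA      = list(threshold = 0.3, upsample_pct = 200, decimate_fraction = 0))

#' Build and validate a pipeline run configuration
#'
#' @param input study directory (as laid out by [write_fixture_study()]) or
#'   NULL to synthesise in memory.
#' @param output run output directory.
#' @param structures structures to process.
#' @param mesh_params per-structure list(threshold, upsample_pct,
#'   decimate_fraction); defaults follow the atlas recipe.
#' @param min_count,tie_policy parcellation parameters.
#' @param n_seeds_per_vertex seeds per vertex when synthesising streamlines.
#' @param correction,family_size stats battery options.
#' @param classifiers named list of [classifier_spec()]-argument lists (the
#'   feature column may be given as `feature` plus covariate names).
#' @param seed master seed.
#' @param phantom,cohort,effect synthio specs used when `input` is NULL.
#' @return validated config (class `run_config`).
#' @export
run_config <- function(input = NULL, output = tempfile("subparc_run_"),
                       structures = "SNc", mesh_params = MESH_DEFAULTS,
                       min_count = 10L, tie_policy = "lowest",
                       n_seeds_per_vertex = 50L,
                       correction = "bonferroni", family_size = 96,
                       classifiers = list(), seed = 1L,
                       phantom = phantom_spec(),
                       cohort = cohort_spec(n = c(HC = 6L, iRBD = 6L, ePD = 6L)),
                       effect = effect_spec()) {
  if (!is.null(input) && !dir.exists(input))
    abort_config(sprintf("run_config: input directory not found: %s", input))
  for (st in structures) if (is.null(mesh_params[[st]]))
    abort_config(sprintf("run_config: no mesh parameters for structure %s", st))
  if (min_count < 1) abort_config("run_config: min_count must be >= 1")
  cfg <- structure(list(input = input, output = output, structures = structures,
                        mesh_params = mesh_params, min_count = as.integer(min_count),
                        tie_policy = tie_policy,
                        n_seeds_per_vertex = as.integer(n_seeds_per_vertex),
                        correction = correction, family_size = family_size,
                        classifiers = classifiers, seed = as.integer(seed),
                        phantom = phantom, cohort = cohort, effect = effect),
                   class = "run_config")
  cfg
}

log_line <- function(con, stage, status, ...) {
  rec <- c(list(ts = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), stage = stage,
                status = status), list(...))
  writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con)
}

# content-keyed stage cache: recompute only when the key changes
stage_cached <- function(cache_dir, name, key, compute, log_con) {
  f <- file.path(cache_dir, paste0(name, "-", hash_obj(key), ".rds"))
  if (file.exists(f)) {
    log_line(log_con, name, "cache-hit", path = f)
    return(readRDS(f))
  }
  t0 <- proc.time()[["elapsed"]]
  val <- compute()
  saveRDS(val, f, version = 2)
  log_line(log_con, name, "computed", seconds = round(proc.time()[["elapsed"]] - t0, 3))
  val
}

#' Run the full pipeline
#'
#' Stages: atlas -> template meshes -> per-subject maps and streamlines ->
#' parcellation -> feature table -> statistical battery -> classifiers.
#' Deterministic given (inputs, config, seed); stage artefacts are cached
#' under `output/cache` keyed by content hashes and reused when inputs are
#' unchanged. A JSON-lines log with per-stage timings is written to
#' `output/log.jsonl`, and the resolved config (with hash) to
#' `output/config.json`.
#'
#' @param cfg a [run_config()].
#' @return list: feature table, battery report, classifier reports, paths.
#' @export
run_pipeline <- function(cfg) {
  dir.create(cfg$output, recursive = TRUE, showWarnings = FALSE)
  cache <- file.path(cfg$output, "cache")
  dir.create(cache, showWarnings = FALSE)
  log_con <- file(file.path(cfg$output, "log.jsonl"), "a")
  on.exit(close(log_con))
  cfg_hash <- hash_obj(unclass(cfg)[setdiff(names(cfg), "output")])
  jsonlite::write_json(list(config_hash = cfg_hash,
                            resolved = rapply(unclass(cfg), as.character, how = "unlist")),
                       file.path(cfg$output, "config.json"), auto_unbox = TRUE)
  stage <- "init"
  withCallingHandlers({
    # ---- atlas -------------------------------------------------------------
    stage <- "atlas"
    atlas <- stage_cached(cache, "atlas", list(cfg$input, cfg$phantom), function() {
      if (is.null(cfg$input)) generate_atlas(cfg$phantom)
      else read_study_atlas(file.path(cfg$input, "atlas"))
    }, log_con)
    # ---- cohort ------------------------------------------------------------
    stage <- "cohort"
    cohort <- stage_cached(cache, "cohort", list(cfg$input, cfg$cohort), function() {
      if (is.null(cfg$input)) generate_cohort(cfg$cohort)
      else read.csv(file.path(cfg$input, "participants.csv"), stringsAsFactors = FALSE)
    }, log_con)
    # ---- template meshes ---------------------------------------------------
    stage <- "surface"
    meshes <- stage_cached(cache, "meshes", list(atlas$spec %||% atlas, cfg$structures, cfg$mesh_params), function() {
      out <- list()
      for (st in cfg$structures) for (h in c("L", "R")) {
        mp <- cfg$mesh_params[[st]]
        out[[paste(st, h, sep = "_")]] <-
          extract_surface(atlas$prob[[paste(st, h, sep = "_")]], mp$threshold,
                          mp$upsample_pct, mp$decimate_fraction, st, h)
      }
      out
    }, log_con)
    # ---- per-subject data + parcellation + features ------------------------
    stage <- "features"
    features <- stage_cached(cache, "features",
                             list(cfg$input, cfg$phantom, cfg$cohort, cfg$effect,
                                  cfg$structures, cfg$mesh_params, cfg$min_count,
                                  cfg$tie_policy, cfg$n_seeds_per_vertex, cohort), function() {
      per_subject <- list()
      for (i in seq_len(nrow(cohort))) {
        sid <- cohort$subject[i]
        if (is.null(cfg$input)) {
          maps <- generate_subject_maps(atlas, cfg$effect, cohort$group[i],
                                        derive_seed(cfg$phantom$seed, "maps", sid),
                                        subject_factor = exp((cfg$effect$subject_sd %||% 0) *
                                                               cohort$subject_intercept[i]))
          md <- maps$md; fa <- maps$fa
          streams <- list()
          for (nm in names(meshes)) {
            prof <- truth_profile(cfg$phantom, meshes[[nm]], dominant = 0.85)
            streams[[nm]] <- generate_streamlines(meshes[[nm]], atlas$cortical_labels, prof,
                                                  cfg$n_seeds_per_vertex,
                                                  seed = derive_seed(cfg$phantom$seed, "streams", sid, nm))
          }
        } else {
          sdir <- file.path(cfg$input, sid, "dwi")
          md <- read_nifti(file.path(sdir, paste0(sid, "_MD.nii.gz")), "MD")
          fa <- read_nifti(file.path(sdir, paste0(sid, "_FA.nii.gz")), "FA")
          if (max(abs(md$affine - fa$affine)) > 1e-6)
            abort_data(sprintf("affine mismatch between MD and FA maps of %s", sid))
          streams <- list()
          for (nm in names(meshes)) {
            f <- file.path(sdir, paste0(sid, "_", nm, ".tck"))
            s <- read_tck(f)
            seedf <- file.path(sdir, paste0(sid, "_", nm, "_seeds.csv"))
            if (file.exists(seedf)) {
              s$seed_vertex <- read.csv(seedf)$seed_vertex
            } else {
              V <- nrow(meshes[[nm]]$vertices)
              if (n_streamlines(s) %% V != 0)
                abort_data(sprintf("no seed-vertex sidecar for %s and streamline count %d is not a multiple of the vertex count %d",
                                   basename(f), n_streamlines(s), V))
              s$seed_vertex <- rep(seq_len(V), each = n_streamlines(s) %/% V)
            }
            if (length(s$seed_vertex) != n_streamlines(s) ||
                max(s$seed_vertex) > nrow(meshes[[nm]]$vertices))
              abort_data(sprintf("seed-vertex annotations for %s do not match the %s mesh",
                                 basename(f), nm))
            streams[[nm]] <- s
          }
        }
        parcs <- list()
        for (nm in names(meshes)) {
          counts <- count_connections(streams[[nm]], atlas$cortical_labels,
                                      n_vertices = nrow(meshes[[nm]]$vertices),
                                      n_targets = length(structure_targets(meshes[[nm]]$structure)))
          parcs[[nm]] <- assign_subregions(counts, cfg$min_count, cfg$tie_policy)
        }
        per_subject[[sid]] <- list(meshes = meshes, parcs = parcs, streams = streams,
                                   md = md, fa = fa)
      }
      build_feature_table(cohort, per_subject, atlas$cortical_labels)
    }, log_con)
    write_feature_table(features, file.path(cfg$output, "features.csv"))
    # ---- statistics --------------------------------------------------------
    stage <- "stats"
    battery <- stage_cached(cache, "battery",
                            list(features, cohort, cfg$correction, cfg$family_size), function() {
      run_group_battery(features, cohort, correction = cfg$correction,
                        family_size = cfg$family_size)
    }, log_con)
    utils::write.csv(battery$omnibus, file.path(cfg$output, "stats_omnibus.csv"), row.names = FALSE)
    if (!is.null(battery$pairwise))
      utils::write.csv(battery$pairwise, file.path(cfg$output, "stats_pairwise.csv"), row.names = FALSE)
    # ---- classifiers -------------------------------------------------------
    stage <- "classify"
    reports <- list()
    merged <- merge(features, cohort, by = "subject")
    for (nm in names(cfg$classifiers)) {
      args <- cfg$classifiers[[nm]]
      args$seed <- args$seed %||% derive_seed(cfg$seed, "classifier", nm)
      spec <- do.call(classifier_spec, args[setdiff(names(args), c("positive_groups", "negative_groups"))])
      rep_ <- run_classifier(merged, spec,
                             positive_groups = args$positive_groups %||% spec$positive,
                             negative_groups = args$negative_groups)
      reports[[nm]] <- rep_
      jsonlite::write_json(classifier_report_json(rep_),
                           file.path(cfg$output, paste0("classifier_", nm, ".json")),
                           auto_unbox = TRUE, digits = NA)
    }
    log_line(log_con, "done", "ok")
    list(features = features, battery = battery, classifiers = reports,
         cohort = cohort, atlas = atlas, meshes = meshes, output = cfg$output)
  }, error = function(e) {
    log_line(log_con, stage, "error", message = conditionMessage(e))
    stop(errorCondition(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
                        class = class(e)))
  })
}

classifier_report_json <- function(x) {
  list(n_train = x$n_train, n_test = x$n_test,
       cv_best_auc = x$cv$best_auc, best_params = x$cv$best_params,
       test_auc = x$test_auc, f1_threshold = x$f1_threshold,
       report_default = x$report_default, report_f1 = x$report_f1,
       bootstrap = list(mean_auc = x$bootstrap$mean_auc,
                        ci_lower = x$bootstrap$ci[1], ci_upper = x$bootstrap$ci[2],
                        min = x$bootstrap$min, max = x$bootstrap$max),
       importance = x$importance)
}

read_study_atlas <- function(adir) {
  probs <- list.files(adir, pattern = "_prob\\.nii\\.gz$", full.names = TRUE)
  prob <- list()
  for (f in probs)
    prob[[sub("_prob\\.nii\\.gz$", "", basename(f))]] <- read_nifti(f, "prob")
  list(prob = prob,
       cortical_labels = read_nifti(file.path(adir, "cortical_labels.nii.gz"), "label"),
       spec = NULL)
}

#' Command-line interface
#'
#' Verbs: `simulate` (write a toy study), `run` (full pipeline on a config
#' JSON), `fixtures` (alias of simulate). Exit codes: 0 ok, 2 config error,
#' 3 data error, 4 statistical precondition failure.
#'
#' @param args character vector (default `commandArgs(trailingOnly = TRUE)`).
#' @return exit status, invisibly.
#' @export
subparc_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (!length(args)) stop(errorCondition("usage: subparc <simulate|fixtures|run> ...",
                                           class = "subparc_config_error"))
    verb <- args[1]
    rest <- args[-1]
    getopt <- function(flag, default) {
      i <- which(rest == flag)
      if (length(i)) rest[i[1] + 1] else default
    }
    if (verb %in% c("simulate", "fixtures")) {
      out <- getopt("--out", "subparc_toy_study")
      seedv <- as.integer(getopt("--seed", "1"))
      write_fixture_study(out, phantom = phantom_spec(seed = seedv))
      message("wrote toy study to ", out)
    } else if (verb == "run") {
      cfgf <- getopt("--config", NULL)
      if (is.null(cfgf)) abort_config("run: --config <file.json> required")
      j <- jsonlite::read_json(cfgf, simplifyVector = TRUE)
      cfg <- do.call(run_config, j)
      run_pipeline(cfg)
      message("run complete: ", cfg$output)
    } else abort_config(sprintf("unknown verb '%s'", verb))
    0L
  },
  subparc_config_error = function(e) { message(conditionMessage(e)); 2L },
  subparc_data_error = function(e) { message(conditionMessage(e)); 3L },
  subparc_stat_error = function(e) { message(conditionMessage(e)); 4L },
  error = function(e) { message(conditionMessage(e)); 1L })
  invisible(status)
}
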