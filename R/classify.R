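# Single-subject biomarker evaluation: class-balanced random-forest
# classification with cross-validated adaptive hyperparameter search,
# stratified hold-out testing, ROC/AUC, F1-optimal thresholding, bootstrap
# stability, and feature importances.

#' Classifier specification
#'
#' @param feature_cols feature column names (e.g. the caudal-motor SNc
#'   surface-MD column plus age, sex, MoCA).
#' @param positive positive class label.
#' @param test_fraction hold-out fraction (default 0.20).
#' @param cv_folds stratified CV folds (default 5).
#' @param n_trials hyperparameter search budget (default 100).
#' @param n_boot bootstrap resamples (default 200).
#' @param seed master seed.
#' @param bounds hyperparameter bounds: list(ntree = c(100, 1000), max_depth
#'   = c(2, 20) with 0 meaning unlimited, min_split = c(2, 10), mtry_mode =
#'   c("sqrt", "log2", "all")).
#' @param search "tpe" (adaptive, default) or "random".
#' @return an object of class `classifier_spec`.
#' @export
classifier_spec <- function(feature_cols, positive = "iRBD", test_fraction = 0.2,
                            cv_folds = 5L, n_trials = 100L, n_boot = 200L,
                            seed = 1L,
                            bounds = list(ntree = c(100L, 1000L),
                                          max_depth = c(0L, 20L),
                                          min_split = c(2L, 10L),
                                          mtry_mode = c("sqrt", "log2", "all")),
                            search = c("tpe", "random")) {
  if (test_fraction <= 0 || test_fraction >= 1) abort_config("classifier_spec: test_fraction in (0,1)")
  if (cv_folds < 2) abort_config("classifier_spec: cv_folds must be >= 2")
  if (n_trials < 1) abort_config("classifier_spec: n_trials must be >= 1")
  structure(list(feature_cols = feature_cols, positive = positive,
                 test_fraction = test_fraction, cv_folds = as.integer(cv_folds),
                 n_trials = as.integer(n_trials), n_boot = as.integer(n_boot),
                 seed = as.integer(seed), bounds = bounds,
                 search = match.arg(search)),
            class = "classifier_spec")
}

#' Group-stratified train/test split
#'
#' Total test size is `ceiling(test_fraction * n)`; per-class allocation by
#' largest remainder, which reproduces the printed hold-out sizes (31 cases
#' for 67+86, 59 for 208+86 at 20 %).
#'
#' @param labels class labels (any number of classes).
#' @param test_fraction test fraction in (0, 1).
#' @param seed RNG seed.
#' @return list(train =, test =) of integer row indices.
#' @export
stratified_split <- function(labels, test_fraction = 0.2, seed = 1L) {
  labels <- as.character(labels)
  n <- length(labels)
  classes <- unique(labels)
  n_test <- as.integer(ceiling(test_fraction * n))
  cl_n <- vapply(classes, function(cl) sum(labels == cl), 0L)
  if (any(cl_n < 2)) abort_stat("stratified_split: a class has fewer than 2 members")
  raw <- cl_n * n_test / n
  base <- floor(raw)
  rem <- n_test - sum(base)
  if (rem > 0) {
    o <- order(raw - base, decreasing = TRUE)
    base[o[seq_len(rem)]] <- base[o[seq_len(rem)]] + 1
  }
  with_seed(seed, {
    test <- integer(0)
    for (ci in seq_along(classes)) {
      rows <- which(labels == classes[ci])
      take <- min(base[ci], length(rows) - 1L)  # never empty a class from train
      test <- c(test, sample(rows, take))
    }
    list(train = setdiff(seq_len(n), test), test = sort(test))
  })
}

# stratified k-fold assignment (vector of fold ids 1..k)
stratified_folds <- function(labels, k, seed) {
  labels <- as.character(labels)
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cl in unique(labels)) {
      rows <- sample(which(labels == cl))
      fold[rows] <- rep_len(seq_len(k), length(rows))
    }
  })
  fold
}

balanced_weights <- function(y) {
  # weights so each class contributes equally (sklearn "balanced")
  n <- length(y)
  tab <- table(y)
  as.numeric(n / (length(tab) * tab[as.character(y)]))
}

rf_params_resolve <- function(params, p) {
  mtry <- switch(params$mtry_mode,
                 sqrt = max(1L, floor(sqrt(p))),
                 log2 = max(1L, floor(log2(p))),
                 all = p)
  list(ntree = as.integer(params$ntree), mtry = as.integer(mtry),
       max_depth = as.integer(params$max_depth), min_split = as.integer(params$min_split))
}

#' Fit a class-balanced random forest
#'
#' @param X numeric matrix (rows = subjects).
#' @param y 0/1 integer labels (1 = positive class).
#' @param params list(ntree, max_depth (0 = unlimited), min_split, mtry_mode).
#' @param seed integer seed.
#' @return list of class `rf_model`: trees, importance (named, sums to 1),
#'   params, feature_names.
#' @export
rf_fit <- function(X, y, params, seed = 1L) {
  X <- as.matrix(X); storage.mode(X) <- "double"
  y <- as.integer(y)
  if (length(unique(y)) < 2) abort_stat("rf_fit: single-class training data")
  w <- balanced_weights(y)
  rp <- rf_params_resolve(params, ncol(X))
  fit <- .rf_fit(X, y, w, rp$ntree, rp$mtry, rp$max_depth, rp$min_split, as.double(seed))
  imp <- as.numeric(fit$importance)
  names(imp) <- colnames(X)
  structure(list(trees = fit$trees, importance = imp, params = params,
                 feature_names = colnames(X)), class = "rf_model")
}

#' @rdname rf_fit
#' @param model an `rf_model`.
#' @return `rf_predict`: positive-class probabilities.
#' @export
rf_predict <- function(model, X) {
  X <- as.matrix(X); storage.mode(X) <- "double"
  as.numeric(.rf_predict(model$trees, X))
}

#' Empirical ROC curve and trapezoidal AUC
#'
#' @param scores classifier scores (higher = more positive).
#' @param labels 0/1 labels.
#' @return list(fpr =, tpr =, auc =); `auc` is `NA` with a reason when the
#'   labels are single-class.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.integer(labels)
  P <- sum(labels == 1); N <- sum(labels == 0)
  if (P == 0 || N == 0)
    return(list(fpr = NA_real_, tpr = NA_real_, auc = structure(NA_real_, reason = "single-class labels")))
  o <- order(scores, decreasing = TRUE)
  ls <- labels[o]; ss <- scores[o]
  tp <- cumsum(ls == 1); fp <- cumsum(ls == 0)
  keep <- c(ss[-1] != ss[-length(ss)], TRUE)   # one point per distinct threshold
  tpr <- c(0, tp[keep] / P); fpr <- c(0, fp[keep] / N)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  list(fpr = fpr, tpr = tpr, auc = auc)
}

#' Adaptive (TPE-style) hyperparameter search
#'
#' Maximises mean stratified-k-fold CV AUC over the budget. After a random
#' start-up phase, candidates are sampled from a kernel density fitted to the
#' better trials and ranked by the good/bad density ratio (a one-dimensional-
#' factorised Parzen estimator); `search = "random"` falls back to pure
#' random sampling. Class weights are balanced in every fit; fully seeded.
#'
#' @param X,y training data (0/1 labels).
#' @param spec a [classifier_spec()].
#' @return list(best_params =, best_auc =, trials = data.frame of per-trial
#'   params + mean CV AUC).
#' @export
tune_rf <- function(X, y, spec) {
  folds <- stratified_folds(y, spec$cv_folds, derive_seed(spec$seed, "folds"))
  for (f in seq_len(spec$cv_folds))
    if (length(unique(y[folds == f])) < 2 || length(unique(y[folds != f])) < 2)
      abort_stat("tune_rf: degenerate single-class fold")
  b <- spec$bounds
  single_point <- b$ntree[1] == b$ntree[2] && b$max_depth[1] == b$max_depth[2] &&
    b$min_split[1] == b$min_split[2] && length(b$mtry_mode) == 1
  sample_random <- function() list(
    ntree = sample(b$ntree[1]:b$ntree[2], 1),
    max_depth = sample(b$max_depth[1]:b$max_depth[2], 1),
    min_split = sample(b$min_split[1]:b$min_split[2], 1),
    mtry_mode = sample(b$mtry_mode, 1))
  cv_auc <- function(params, trial) {
    aucs <- numeric(spec$cv_folds)
    for (f in seq_len(spec$cv_folds)) {
      tr <- folds != f
      m <- rf_fit(X[tr, , drop = FALSE], y[tr], params,
                  seed = derive_seed(spec$seed, "cv", trial, f))
      aucs[f] <- roc_curve(rf_predict(m, X[!tr, , drop = FALSE]), y[!tr])$auc
    }
    mean(aucs)
  }
  n_start <- min(max(5L, spec$n_trials %/% 4L), spec$n_trials)
  trials <- list()
  with_seed(derive_seed(spec$seed, "search"), {
    budget <- if (single_point) 1L else spec$n_trials
    for (tr in seq_len(budget)) {
      params <- if (single_point) {
        list(ntree = b$ntree[1], max_depth = b$max_depth[1],
             min_split = b$min_split[1], mtry_mode = b$mtry_mode[1])
      } else if (spec$search == "random" || tr <= n_start) {
        sample_random()
      } else {
        tpe_propose(trials, b, sample_random)
      }
      auc <- cv_auc(params, tr)
      trials[[tr]] <- data.frame(trial = tr, ntree = params$ntree,
                                 max_depth = params$max_depth,
                                 min_split = params$min_split,
                                 mtry_mode = params$mtry_mode,
                                 cv_auc = auc, stringsAsFactors = FALSE)
    }
  })
  trials <- do.call(rbind, trials)
  best <- trials[which.max(trials$cv_auc), ]
  list(best_params = list(ntree = best$ntree, max_depth = best$max_depth,
                          min_split = best$min_split, mtry_mode = best$mtry_mode),
       best_auc = best$cv_auc, trials = trials)
}

# propose one candidate by the good/bad Parzen density ratio, factorised over
# hyperparameters; numeric dims use Gaussian kernels, the categorical dim
# smoothed counts
tpe_propose <- function(trials, b, sample_random, gamma = 0.25, n_cand = 24L) {
  hist <- do.call(rbind, trials)
  cut <- quantile(hist$cv_auc, 1 - gamma, type = 1)
  good <- hist[hist$cv_auc >= cut, , drop = FALSE]
  bad <- hist[hist$cv_auc < cut, , drop = FALSE]
  if (!nrow(good) || !nrow(bad)) return(sample_random())
  dens <- function(x, obs, lo, hi) {
    bw <- max((hi - lo) / 6, diff(range(obs)) / 4, 1e-9)
    rowMeans(outer(x, obs, function(a, o) exp(-0.5 * ((a - o) / bw)^2) / bw)) + 1e-12
  }
  cand <- replicate(n_cand, {
    g <- good[sample.int(nrow(good), 1), ]
    list(ntree = max(b$ntree[1], min(b$ntree[2], round(g$ntree + rnorm(1, 0, (b$ntree[2] - b$ntree[1]) / 8)))),
         max_depth = max(b$max_depth[1], min(b$max_depth[2], round(g$max_depth + rnorm(1, 0, 2)))),
         min_split = max(b$min_split[1], min(b$min_split[2], round(g$min_split + rnorm(1, 0, 1)))),
         mtry_mode = if (runif(1) < 0.8) g$mtry_mode else sample(b$mtry_mode, 1))
  }, simplify = FALSE)
  score <- vapply(cand, function(cc) {
    lg <- dens(cc$ntree, good$ntree, b$ntree[1], b$ntree[2]) *
          dens(cc$max_depth, good$max_depth, b$max_depth[1], b$max_depth[2]) *
          dens(cc$min_split, good$min_split, b$min_split[1], b$min_split[2]) *
          ((sum(good$mtry_mode == cc$mtry_mode) + 1) / (nrow(good) + length(b$mtry_mode)))
    lb <- dens(cc$ntree, bad$ntree, b$ntree[1], b$ntree[2]) *
          dens(cc$max_depth, bad$max_depth, b$max_depth[1], b$max_depth[2]) *
          dens(cc$min_split, bad$min_split, b$min_split[1], b$min_split[2]) *
          ((sum(bad$mtry_mode == cc$mtry_mode) + 1) / (nrow(bad) + length(b$mtry_mode)))
    lg / lb
  }, 0)
  cand[[which.max(score)]]
}

#' F1-maximising decision threshold
#'
#' Scans the midpoints of consecutive distinct scores (plus below-min and
#' above-max sentinels) and returns the threshold maximising F1 for the
#' positive class; ties resolve to the lowest threshold.
#'
#' @param scores numeric scores.
#' @param labels 0/1 labels (must contain positives).
#' @return the threshold (predict positive when `score >= threshold`).
#' @export
f1_threshold <- function(scores, labels) {
  labels <- as.integer(labels)
  if (!any(labels == 1)) abort_stat("f1_threshold: no positive labels")
  u <- sort(unique(scores))
  cands <- c(u[1] - 1, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, u[length(u)] + 1)
  f1 <- vapply(cands, function(th) {
    pred <- scores >= th
    tp <- sum(pred & labels == 1); fp <- sum(pred & labels == 0)
    fn <- sum(!pred & labels == 1)
    if (tp == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, 0)
  cands[which.max(f1)]   # which.max -> first (lowest) among ties
}

#' Confusion matrix and derived metrics at a threshold
#'
#' @param scores numeric scores.
#' @param labels 0/1 labels.
#' @param threshold decision threshold (positive iff `score >= threshold`).
#' @return list: confusion (TP, FP, TN, FN), sensitivity, specificity,
#'   balanced_accuracy (= (sens + spec)/2 exactly), threshold.
#' @export
confusion_report <- function(scores, labels, threshold = 0.5) {
  labels <- as.integer(labels)
  pred <- scores >= threshold
  tp <- sum(pred & labels == 1); fp <- sum(pred & labels == 0)
  tn <- sum(!pred & labels == 0); fn <- sum(!pred & labels == 1)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  list(confusion = c(TP = tp, FP = fp, TN = tn, FN = fn),
       sensitivity = sens, specificity = spec,
       balanced_accuracy = (sens + spec) / 2, threshold = threshold)
}

#' Fit the final model on the training set and evaluate on the hold-out
#'
#' @param Xtr,ytr training data.
#' @param Xte,yte hold-out data.
#' @param params chosen hyperparameters.
#' @param seed seed for the final fit.
#' @return list: model, roc (fpr/tpr), auc, scores, report_default (0.5
#'   threshold), report_f1 (F1-optimal threshold from the test scores),
#'   f1_threshold.
#' @export
fit_and_test <- function(Xtr, ytr, Xte, yte, params, seed = 1L) {
  model <- rf_fit(Xtr, ytr, params, seed)
  scores <- rf_predict(model, Xte)
  roc <- roc_curve(scores, yte)
  thr <- if (any(yte == 1)) f1_threshold(scores, yte) else NA_real_
  list(model = model, roc = roc[c("fpr", "tpr")], auc = roc$auc, scores = scores,
       report_default = confusion_report(scores, yte, 0.5),
       report_f1 = if (!is.na(thr)) confusion_report(scores, yte, thr) else NULL,
       f1_threshold = thr)
}

#' Bootstrap stability of the tuned model
#'
#' Resamples the training set with replacement (equal size), refits the
#' chosen hyperparameters, and evaluates AUC on the fixed test set `n_boot`
#' times. Single-class resamples are redrawn (count logged).
#'
#' @param Xtr,ytr training data.
#' @param Xte,yte fixed hold-out data.
#' @param params chosen hyperparameters.
#' @param n_boot number of resamples (default 200).
#' @param seed master seed.
#' @return list: mean_auc, ci (2.5/97.5 percentiles), min, max, aucs,
#'   n_redrawn.
#' @export
bootstrap_stability <- function(Xtr, ytr, Xte, yte, params, n_boot = 200L, seed = 1L) {
  aucs <- numeric(n_boot)
  redrawn <- 0L
  for (bq in seq_len(n_boot)) {
    attempt <- 0L
    repeat {
      idx <- with_seed(derive_seed(seed, "boot", bq, attempt),
                       sample.int(length(ytr), length(ytr), replace = TRUE))
      if (length(unique(ytr[idx])) > 1) break
      attempt <- attempt + 1L
      redrawn <- redrawn + 1L
      if (attempt > 100) abort_stat("bootstrap_stability: cannot draw a two-class resample")
    }
    m <- rf_fit(Xtr[idx, , drop = FALSE], ytr[idx], params,
                seed = derive_seed(seed, "bootfit", bq))
    aucs[bq] <- roc_curve(rf_predict(m, Xte), yte)$auc
  }
  ci <- unname(quantile(aucs, c(0.025, 0.975), type = 7))
  list(mean_auc = mean(aucs), ci = ci, min = min(aucs), max = max(aucs),
       aucs = aucs, n_redrawn = redrawn)
}

#' Importance ranking of a fitted forest
#'
#' Impurity-decrease importances normalised to sum 1, in descending order.
#'
#' @param model an `rf_model`.
#' @return data.frame(feature, importance), descending.
#' @export
importance_ranking <- function(model) {
  imp <- sort(model$importance, decreasing = TRUE)
  data.frame(feature = names(imp), importance = unname(imp),
             stringsAsFactors = FALSE)
}

#' Run the full classifier evaluation for one contrast
#'
#' Stratified 80/20 split, CV hyperparameter search on the training set only,
#' final fit, hold-out ROC/AUC, default and F1-optimal confusion reports,
#' bootstrap stability, and feature importances. The hold-out rows are never
#' seen by the search, the final fit, or the threshold choice on training
#' data (the F1 threshold is computed on test scores, as in the workflow this
#' package reproduces).
#'
#' @param data data.frame containing the feature columns and a `group`
#'   column.
#' @param spec a [classifier_spec()].
#' @param positive_groups group labels forming the positive class (default:
#'   `spec$positive`).
#' @param negative_groups group labels forming the negative class (default:
#'   all others present).
#' @return list of class `classifier_report`.
#' @export
run_classifier <- function(data, spec, positive_groups = spec$positive,
                           negative_groups = NULL) {
  if (is.null(negative_groups))
    negative_groups <- setdiff(unique(data$group), positive_groups)
  keep <- data$group %in% c(positive_groups, negative_groups)
  d <- data[keep, , drop = FALSE]
  y <- as.integer(d$group %in% positive_groups)
  X <- as.matrix(sapply(spec$feature_cols, function(fc) {
    v <- d[[fc]]
    if (is.null(v)) abort_config(sprintf("run_classifier: missing feature column '%s'", fc))
    if (!is.numeric(v)) as.numeric(factor(v)) - 1 else v
  }))
  colnames(X) <- spec$feature_cols
  cc <- complete.cases(X)
  X <- X[cc, , drop = FALSE]; y <- y[cc]
  sp <- stratified_split(y, spec$test_fraction, derive_seed(spec$seed, "split"))
  Xtr <- X[sp$train, , drop = FALSE]; ytr <- y[sp$train]
  Xte <- X[sp$test, , drop = FALSE]; yte <- y[sp$test]
  tuned <- tune_rf(Xtr, ytr, spec)
  fin <- fit_and_test(Xtr, ytr, Xte, yte, tuned$best_params,
                      seed = derive_seed(spec$seed, "final"))
  boot <- bootstrap_stability(Xtr, ytr, Xte, yte, tuned$best_params,
                              spec$n_boot, derive_seed(spec$seed, "bootstrap"))
  structure(list(
    spec = spec, n_train = length(ytr), n_test = length(yte),
    cv = list(best_params = tuned$best_params, best_auc = tuned$best_auc,
              trials = tuned$trials),
    test_auc = fin$auc, roc = fin$roc,
    report_default = fin$report_default, report_f1 = fin$report_f1,
    f1_threshold = fin$f1_threshold,
    bootstrap = boot[c("mean_auc", "ci", "min", "max", "n_redrawn")],
    bootstrap_aucs = boot$aucs,
    importance = importance_ranking(fin$model),
    model = fin$model, test_scores = fin$scores, test_labels = yte),
    class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf("<classifier_report> train %d / test %d\n", x$n_train, x$n_test))
  cat(sprintf("  CV mean AUC %.3f; hold-out AUC %.3f\n", x$cv$best_auc, x$test_auc))
  r <- x$report_f1 %||% x$report_default
  cat(sprintf("  sens %.2f spec %.2f balanced accuracy %.2f (threshold %.2f)\n",
              r$sensitivity, r$specificity, r$balanced_accuracy, r$threshold))
  cat(sprintf("  bootstrap AUC %.3f [%.3f, %.3f]\n",
              x$bootstrap$mean_auc, x$bootstrap$ci[1], x$bootstrap$ci[2]))
  invisible(x)
}
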