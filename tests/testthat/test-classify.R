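test_that("stratified split reproduces the printed hold-out sizes and class ratios", {
  # 67 positives + 86 negatives at 20% -> 31 cases
  lab1 <- c(rep("pos", 67), rep("neg", 86))
  s1 <- stratified_split(lab1, 0.2, seed = 1)
  expect_identical(length(s1$test), 31L)
  # 208 positives + 86 negatives -> 59 cases
  lab2 <- c(rep("pos", 208), rep("neg", 86))
  s2 <- stratified_split(lab2, 0.2, seed = 1)
  expect_identical(length(s2$test), 59L)
  # disjoint, exhaustive, per-class proportions within rounding
  expect_identical(sort(c(s1$train, s1$test)), seq_along(lab1))
  pt <- table(lab1[s1$test]) / table(lab1)
  expect_true(all(abs(pt - 0.2) < 0.05))
  # determinism and seed sensitivity
  expect_identical(stratified_split(lab1, 0.2, seed = 7), stratified_split(lab1, 0.2, seed = 7))
  s3 <- stratified_split(lab1, 0.2, seed = 8)
  expect_false(identical(s1$test, s3$test))
  expect_identical(table(lab1[s3$test]), table(lab1[s1$test]))
  expect_error(stratified_split(c("a", rep("b", 9)), 0.2, 1), class = "subparc_stat_error")
})

test_that("ROC/AUC: trivial cases, closed-form binormal value, monotone invariance", {
  expect_equal(roc_curve(rep(0.5, 10), rep(0:1, 5))$auc, 0.5)
  expect_equal(roc_curve(1:10, c(rep(0, 5), rep(1, 5)))$auc, 1.0)
  expect_true(is.na(roc_curve(1:5, rep(1, 5))$auc))
  set.seed(31)
  n <- 2000
  scores <- c(rnorm(n, 0), rnorm(n, 2))
  labels <- rep(0:1, each = n)
  auc <- roc_curve(scores, labels)$auc
  expect_equal(auc, pnorm(2 / sqrt(2)), tolerance = 0.01)
  # strictly increasing transform leaves the AUC unchanged
  expect_equal(roc_curve(exp(scores / 3), labels)$auc, auc, tolerance = 1e-12)
})

test_that("F1 threshold equals brute-force maximisation and handles edge cases", {
  th <- f1_threshold(c(0.1, 0.4, 0.6, 0.9), c(0, 0, 1, 1))
  expect_equal(th, 0.5)
  r <- confusion_report(c(0.1, 0.4, 0.6, 0.9), c(0, 0, 1, 1), th)
  expect_equal(r$sensitivity, 1); expect_equal(r$specificity, 1)
  # all positives: threshold below the minimum score
  expect_lt(f1_threshold(c(0.3, 0.7), c(1, 1)), 0.3)
  expect_error(f1_threshold(1:3, c(0, 0, 0)), class = "subparc_stat_error")
  set.seed(32)
  for (i in 1:100) {
    n <- sample(5:40, 1)
    sc <- round(runif(n), 2)
    lb <- rbinom(n, 1, 0.4)
    if (!any(lb == 1)) lb[1] <- 1
    th <- f1_threshold(sc, lb)
    f1_at <- function(t) {
      tp <- sum(sc >= t & lb == 1); fp <- sum(sc >= t & lb == 0); fn <- sum(sc < t & lb == 1)
      if (tp == 0) 0 else 2 * tp / (2 * tp + fp + fn)
    }
    grid <- c(sort(unique(sc)) - 1e-9, max(sc) + 1)
    expect_equal(f1_at(th), max(vapply(grid, f1_at, 0)), tolerance = 1e-12)
  }
})

test_that("confusion_report reproduces the printed balanced accuracies", {
  # sens 1.00 / spec 0.82 -> 0.91 ; sens 0.83 / spec 0.88 -> 0.855 ~ 0.86
  scores <- c(rep(1, 9), rep(1, 18), rep(0, 82))
  labels <- c(rep(1, 9), rep(0, 100))
  r <- confusion_report(scores, labels, 0.5)
  expect_equal(r$sensitivity, 1.00)
  expect_equal(r$specificity, 0.82)
  expect_equal(r$balanced_accuracy, 0.91)
  r2 <- list(sensitivity = 0.83, specificity = 0.88)
  expect_equal(round((r2$sensitivity + r2$specificity) / 2, 2), 0.86)
  # TP = FN and TN = FP -> balanced accuracy 0.5
  r3 <- confusion_report(c(1, 0, 1, 0), c(1, 1, 0, 0), 0.5)
  expect_equal(r3$balanced_accuracy, 0.5)
  expect_identical(unname(r3$confusion), c(1L, 1L, 1L, 1L))
})

test_that("random forest: separable data, importances, determinism", {
  set.seed(33)
  n <- 120
  X <- cbind(sig = c(rnorm(n / 2, 0), rnorm(n / 2, 3)),
             n1 = rnorm(n), n2 = rnorm(n), n3 = rnorm(n))
  y <- rep(0:1, each = n / 2)
  params <- list(ntree = 200, max_depth = 0, min_split = 2, mtry_mode = "sqrt")
  m <- rf_fit(X, y, params, seed = 4)
  expect_equal(sum(m$importance), 1, tolerance = 1e-9)
  expect_identical(importance_ranking(m)$feature[1], "sig")
  p <- rf_predict(m, X)
  expect_gte(roc_curve(p, y)$auc, 0.99)
  # same seed -> identical forest output; different seed differs
  m2 <- rf_fit(X, y, params, seed = 4)
  expect_identical(rf_predict(m2, X), p)
  expect_false(identical(rf_predict(rf_fit(X, y, params, seed = 5), X), p))
  expect_error(rf_fit(X, rep(1, n), params), class = "subparc_stat_error")
})

test_that("search: single-point space short-circuits; separable data reaches AUC ~1; no leakage under label permutation", {
  set.seed(34)
  n <- 80
  X <- cbind(f = c(rnorm(n / 2, 0, 0.3), rnorm(n / 2, 4, 0.3)), z = rnorm(n))
  y <- rep(0:1, each = n / 2)
  spec1 <- classifier_spec("f", n_trials = 50, seed = 2,
                           bounds = list(ntree = c(150L, 150L), max_depth = c(4L, 4L),
                                         min_split = c(2L, 2L), mtry_mode = "all"))
  t1 <- tune_rf(X, y, spec1)
  expect_identical(nrow(t1$trials), 1L)   # one effective trial
  expect_identical(t1$best_params$ntree, 150L)
  spec2 <- classifier_spec(c("f", "z"), n_trials = 8, seed = 3,
                           bounds = list(ntree = c(100L, 300L), max_depth = c(2L, 10L),
                                         min_split = c(2L, 6L), mtry_mode = c("sqrt", "all")))
  t2 <- tune_rf(X, y, spec2)
  expect_gte(t2$best_auc, 0.99)
  # permuted labels: best CV AUC stays near chance (no leakage)
  yperm <- sample(y)
  t3 <- tune_rf(X, yperm, spec2)
  expect_gt(t3$best_auc, 0.35); expect_lt(t3$best_auc, 0.68)
  expect_error(tune_rf(X[1:6, ], c(1, 1, 1, 0, 1, 1),
                       classifier_spec("f", cv_folds = 5, n_trials = 2)),
               class = "subparc_stat_error")
})

test_that("fit_and_test and bootstrap behave on trivial and separable data", {
  set.seed(35)
  n <- 60
  Xtr <- cbind(f = c(rnorm(n / 2, 0, 0.3), rnorm(n / 2, 4, 0.3)))
  ytr <- rep(0:1, each = n / 2)
  Xte <- cbind(f = c(rnorm(10, 0, 0.3), rnorm(10, 4, 0.3)))
  yte <- rep(0:1, each = 10)
  params <- list(ntree = 150, max_depth = 0, min_split = 2, mtry_mode = "all")
  ft <- fit_and_test(Xtr, ytr, Xte, yte, params, seed = 6)
  expect_equal(ft$auc, 1.0)
  expect_equal(ft$report_f1$balanced_accuracy, 1.0)
  bs <- bootstrap_stability(Xtr, ytr, Xte, yte, params, n_boot = 25, seed = 7)
  expect_gte(bs$ci[1], 0.9)
  expect_true(bs$ci[1] <= bs$mean_auc && bs$mean_auc <= bs$ci[2])
  expect_identical(length(bs$aucs), 25L)
  # n_boot = 1: degenerate CI equal to the single AUC
  b1 <- bootstrap_stability(Xtr, ytr, Xte, yte, params, n_boot = 1, seed = 8)
  expect_identical(b1$mean_auc, b1$aucs[1])
  expect_identical(b1$ci[1], b1$ci[2])
})

test_that("hold-out rows never influence training artefacts (poisoned-labels audit)", {
  coh <- generate_cohort(cohort_spec(n = c(HC = 30L, iRBD = 20L), seed = 11))
  ft <- simulate_feature_table(coh, effect_spec(groups = "iRBD"), seed = 12)
  d <- merge(ft, coh, by = "subject")
  spec <- classifier_spec(c("SNc_caudal_motor_surface_MD", "age"), positive = "iRBD",
                          n_trials = 4, n_boot = 5, seed = 13)
  y <- as.integer(d$group == "iRBD")
  X <- as.matrix(d[, spec$feature_cols])
  sp <- stratified_split(y, 0.2, derive_seed(spec$seed, "split"))
  tuned1 <- tune_rf(X[sp$train, ], y[sp$train], spec)
  fin1 <- fit_and_test(X[sp$train, ], y[sp$train], X[sp$test, ], y[sp$test],
                       tuned1$best_params, derive_seed(spec$seed, "final"))
  # poison the test labels/features: training artefacts must be unchanged
  y2 <- y; y2[sp$test] <- 1 - y2[sp$test]
  X2 <- X; X2[sp$test, ] <- X2[sp$test, ] * 100
  tuned2 <- tune_rf(X2[sp$train, ], y2[sp$train], spec)
  fin2 <- fit_and_test(X2[sp$train, ], y2[sp$train], X2[sp$test, ], y2[sp$test],
                       tuned2$best_params, derive_seed(spec$seed, "final"))
  expect_identical(tuned2$trials, tuned1$trials)
  expect_identical(fin2$model$trees, fin1$model$trees)
})

test_that("end-to-end recovery: planted feature tops the importances and beats the permutation null", {
  coh <- generate_cohort(cohort_spec(seed = 21))
  ft <- simulate_feature_table(coh, effect_spec(), seed = 22)
  d <- merge(ft, coh, by = "subject")
  d$group <- ifelse(d$group == "HC", "HC", "patient")
  spec <- classifier_spec(c("SNc_caudal_motor_surface_MD", "age", "sex", "moca"),
                          positive = "patient", n_trials = 10, n_boot = 20, seed = 23)
  rep_ <- run_classifier(d, spec)
  expect_identical(rep_$importance$feature[1], "SNc_caudal_motor_surface_MD")
  # permutation null for the hold-out AUC at the chosen hyperparameters
  y <- as.integer(d$group == "patient")
  X <- as.matrix(cbind(d[, "SNc_caudal_motor_surface_MD"], d$age,
                       as.numeric(factor(d$sex)) - 1, d$moca))
  sp <- stratified_split(y, 0.2, derive_seed(23, "split"))
  null_auc <- vapply(1:40, function(i) {
    yp <- subparc:::with_seed(derive_seed(23, "perm", i), sample(y))
    if (length(unique(yp[sp$train])) < 2 || length(unique(yp[sp$test])) < 2) return(0.5)
    fit_and_test(X[sp$train, ], yp[sp$train], X[sp$test, ], yp[sp$test],
                 rep_$cv$best_params, derive_seed(23, "permfit", i))$auc
  }, 0)
  expect_gt(rep_$test_auc, quantile(null_auc, 0.975))
})
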