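test_that("Levene gate: calibration, constructed heteroscedasticity, degenerate input", {
  # equal-variance groups stay on the parametric route in most seeds
  routes <- vapply(1:100, function(s) {
    set.seed(s)
    g <- rep(1:3, each = 200)
    levene_gate(rnorm(600), g)$route
  }, "")
  expect_gte(mean(routes == "parametric"), 0.90)
  # one group's scale x10 triggers the non-parametric route
  set.seed(1)
  g <- rep(1:2, each = 50)
  v <- c(rnorm(50), rnorm(50) * 10)
  expect_identical(levene_gate(v, g)$route, "nonparametric")
  # two identical constant groups: statistic 0, p 1, parametric
  lg <- levene_gate(rep(c(5, 5, 5, 5), 2), rep(1:2, each = 4))
  expect_identical(lg$statistic, 0)
  expect_identical(lg$p, 1)
  expect_identical(lg$route, "parametric")
  expect_error(levene_gate(1:3, c(1, 1, 2)), class = "subparc_stat_error")
})

test_that("ANCOVA reduces to one-way ANOVA without informative covariates", {
  set.seed(21)
  y <- rnorm(60); g <- factor(rep(letters[1:3], 20))
  a <- ancova_group(y, g, NULL)
  f <- anova(lm(y ~ g))
  expect_equal(a$statistic, f[["F value"]][1], tolerance = 1e-8)
  expect_equal(a$p, f[["Pr(>F)"]][1], tolerance = 1e-8)
  # adding a pure-noise covariate changes df but F stays within sampling identity
  cov <- data.frame(age = rnorm(60))
  a2 <- ancova_group(y, g, cov)
  expect_equal(a2$df, c(2, 56))
  # eta2p and MSe match the definitional computation from lm
  m1 <- lm(y ~ age + g, data = cbind(cov, g = g))
  m0 <- lm(y ~ age, data = cov)
  ss_g <- sum(residuals(m0)^2) - sum(residuals(m1)^2)
  expect_equal(a2$eta2p, ss_g / (ss_g + sum(residuals(m1)^2)), tolerance = 1e-10)
  expect_equal(a2$MSe, sum(residuals(m1)^2) / 56, tolerance = 1e-10)
})

test_that("ANCOVA type-I error is calibrated under the null", {
  set.seed(22)
  reps <- 400
  p <- vapply(seq_len(reps), function(i) {
    g <- factor(rep(1:3, c(20, 15, 15)))
    covs <- data.frame(age = rnorm(50, 65, 7), sex = sample(c("M", "F"), 50, TRUE))
    ancova_group(rnorm(50), g, covs)$p
  }, 0)
  rej <- mean(p < 0.05)
  expect_gt(rej, 0.02); expect_lt(rej, 0.09)
  expect_gt(suppressWarnings(ks.test(p, "punif"))$p.value, 0.01)
})

test_that("ANCOVA detects a large planted shift and flags rank deficiency", {
  set.seed(23)
  g <- factor(rep(1:3, each = 20))
  y <- rnorm(60); y[g == 2] <- y[g == 2] + 3
  a <- ancova_group(y, g, data.frame(age = rnorm(60)))
  expect_lt(a$p, 1e-6)
  # pairwise contrasts: printed df convention n_i + n_j - 2
  expect_identical(a$pairwise$df, rep(38, 3))
  expect_lt(a$pairwise$p[a$pairwise$group1 == "1" & a$pairwise$group2 == "2"], 1e-6)
  # site perfectly confounded with group -> explicit aliasing error
  covs <- data.frame(site = as.character(g))
  expect_error(ancova_group(y, g, covs), "aliased", class = "subparc_stat_error")
})

test_that("Kruskal-Wallis H and Dunn z match hand computation and base R", {
  kd <- kruskal_dunn(c(1, 2, 3, 4, 5, 6, 7, 8, 9), rep(1:3, each = 3))
  expect_equal(kd$statistic, 7.2, tolerance = 1e-12)
  expect_equal(kd$p, pchisq(7.2, 2, lower.tail = FALSE), tolerance = 1e-12)
  expect_identical(kruskal_dunn(rep(1:2, 10), rep(1:2, each = 10))$statistic >= 0, TRUE)
  # identical groups: H = 0
  expect_identical(kruskal_dunn(rep(5, 12), rep(1:3, each = 4))$statistic, 0)
  # ties: H matches stats::kruskal.test to 1e-10; Dunn z matches the
  # definitional rank formula
  set.seed(24)
  for (i in 1:20) {
    y <- sample(1:8, 30, TRUE)
    g <- rep(1:3, each = 10)
    kd2 <- kruskal_dunn(y, g)
    bt <- kruskal.test(y, g)
    expect_equal(kd2$statistic, unname(bt$statistic), tolerance = 1e-10)
    expect_equal(kd2$p, bt$p.value, tolerance = 1e-10)
    r <- rank(y); N <- 30
    ties <- table(y); TIE <- sum(ties^3 - ties)
    s2 <- N * (N + 1) / 12 - TIE / (12 * (N - 1))
    z12 <- (mean(r[g == 1]) - mean(r[g == 2])) / sqrt(s2 * (1 / 10 + 1 / 10))
    expect_equal(kd2$pairwise$z[1], z12, tolerance = 1e-10)
  }
})

test_that("p-value adjustment matches brute-force definitions; BH rejects a superset", {
  # worked example: p = 0.0004 with m = 96 -> 0.0384, significant at 0.05
  expect_equal(adjust_pvalues(0.0004, "bonferroni", 96), 0.0384)
  expect_identical(adjust_pvalues(1, "bonferroni", 96), 1)
  expect_identical(adjust_pvalues(1, "BH", 96), 1)
  expect_error(adjust_pvalues(1.2, "bonferroni"), class = "subparc_stat_error")
  set.seed(25)
  for (i in 1:100) {
    n <- sample(3:25, 1)
    m <- sample(c(n, 96), 1)
    p <- runif(n)^2
    bon <- adjust_pvalues(p, "bonferroni", m)
    bh <- adjust_pvalues(p, "benjamini-hochberg", m)
    expect_equal(bon, pmin(1, p * m))
    # BH oracle straight from the step-up definition
    o <- order(p)
    padj <- numeric(n)
    running <- 1
    for (j in n:1) {
      running <- min(running, m * p[o[j]] / j)
      padj[o[j]] <- running
    }
    expect_equal(bh, padj, tolerance = 1e-12)
    expect_true(all(bh <= bon + 1e-12))     # BH rejections are a superset
    expect_true(all(bh >= p - 1e-12) && all(bon >= p - 1e-12))
  }
})

test_that("BIC Bayes factor points toward the null on null data and the alternative on shifted data", {
  null_bf <- vapply(1:60, function(s) {
    set.seed(s)
    g <- rep(c("A", "B"), each = 60)
    covs <- data.frame(age = rnorm(120, 65, 7), sex = sample(c("M", "F"), 120, TRUE))
    bayes_equivalence(rnorm(120), g, covs)$BF10
  }, 0)
  expect_lt(median(null_bf), 1)
  alt_bf <- vapply(1:60, function(s) {
    set.seed(s + 500)
    g <- rep(c("A", "B"), each = 60)
    y <- rnorm(120); y[61:120] <- y[61:120] + 2
    bayes_equivalence(y, g, data.frame(age = rnorm(120)))$BF10
  }, 0)
  expect_gte(mean(alt_bf > 3), 0.95)
  # identical data under shuffled duplicate labels: BF10 < 1
  set.seed(26)
  y <- rnorm(40)
  expect_lt(bayes_equivalence(c(y, y), sample(rep(c("A", "B"), 40)))$BF10, 1)
  expect_error(bayes_equivalence(rnorm(4), c("A", "A", "B", "B"),
                                 data.frame(a = rnorm(4), b = rnorm(4))),
               class = "subparc_stat_error")
})

test_that("Spearman: monotone extremes, exact small-sample p, degenerate input", {
  expect_identical(spearman_assoc(1:8, (1:8)^3)$r_s, 1)
  expect_identical(spearman_assoc(1:8, -(1:8))$r_s, -1)
  expect_identical(spearman_assoc(1:3, 3:1)$reason, "n < 4")
  expect_identical(spearman_assoc(1:5, rep(2, 5))$reason, "zero variance")
  # n = 6: p matches exhaustive enumeration over all 720 rank permutations
  set.seed(27)
  for (i in 1:10) {
    x <- rnorm(6); y <- rnorm(6)
    sp <- spearman_assoc(x, y)
    perms <- subparc:::all_perms(6)
    rx <- rank(x); ry <- rank(y)
    rs_all <- apply(perms, 1, function(pp) cor(rx, ry[pp]))
    expect_equal(sp$p, mean(abs(rs_all) >= abs(sp$r_s) - 1e-12), tolerance = 1e-12)
    ct <- cor.test(x, y, method = "spearman", exact = TRUE)
    expect_equal(sp$r_s, unname(ct$estimate))
    expect_equal(sp$p, ct$p.value, tolerance = 1e-10)
  }
})

test_that("rank statistics are invariant under strictly monotone transforms", {
  set.seed(28)
  y <- rnorm(45); g <- rep(1:3, each = 15)
  x2 <- rnorm(45)
  for (f in list(function(v) exp(v), function(v) v^3, function(v) atan(v))) {
    expect_equal(kruskal_dunn(f(y), g)$statistic, kruskal_dunn(y, g)$statistic)
    expect_equal(spearman_assoc(f(y), x2)$r_s, spearman_assoc(y, x2)$r_s)
  }
})

test_that("battery: fast path equals the per-feature path; skipped features are explicit", {
  coh <- generate_cohort(cohort_spec(n = c(HC = 15L, iRBD = 10L, ePD = 10L), seed = 5))
  ft <- simulate_feature_table(coh, effect_spec(shift = 0.05), seed = 6)
  slow <- run_group_battery(ft, coh, family_size = 96)
  fast <- run_group_battery(ft, coh, family_size = 96, fast = TRUE)
  expect_equal(fast$omnibus$p, slow$omnibus$p, tolerance = 1e-10)
  expect_identical(fast$omnibus$route, slow$omnibus$route)
  expect_equal(fast$omnibus$p_adj, slow$omnibus$p_adj, tolerance = 1e-10)
  # all-NA feature becomes a skipped row, not an error
  ft$SNc_total_surface_FA <- NA_real_
  rep2 <- run_group_battery(ft, coh, family_size = 96)
  expect_identical(rep2$omnibus$route[rep2$omnibus$feature == "SNc_total_surface_FA"],
                   "skipped")
})
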