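# Group-level statistical battery: Levene-gated ANCOVA vs Kruskal-Wallis
# with Dunn post-hocs, Bonferroni / Benjamini-Hochberg family-wise
# corrections, BIC-approximated Bayesian equivalence ANCOVA, and Spearman
# clinical correlations.

#' Levene gate: parametric or non-parametric route
#'
#' Brown-Forsythe variant (median centring): a one-way ANOVA on the absolute
#' deviations from group medians. The non-parametric route is taken iff the
#' Levene p-value is below `alpha`.
#'
#' @param values numeric vector.
#' @param group factor/character of the same length (>= 2 groups, >= 2
#'   observations each).
#' @param alpha gate level (default 0.05).
#' @return list(route = "parametric"|"nonparametric", statistic =, df =, p =).
#' @export
levene_gate <- function(values, group, alpha = 0.05) {
  group <- factor(group)
  if (nlevels(group) < 2) abort_stat("levene_gate: need >= 2 groups")
  ng <- table(group)
  if (any(ng < 2)) abort_stat("levene_gate: every group needs >= 2 observations")
  med <- tapply(values, group, median)
  z <- abs(values - med[group])
  k <- nlevels(group); N <- length(values)
  zbar_g <- tapply(z, group, mean); zbar <- mean(z)
  ssb <- sum(ng * (zbar_g - zbar)^2)
  ssw <- sum((z - zbar_g[group])^2)
  if (ssw == 0 && ssb == 0) {
    stat <- 0; p <- 1
  } else if (ssw == 0) {
    stat <- Inf; p <- 0
  } else {
    stat <- (ssb / (k - 1)) / (ssw / (N - k))
    p <- pf(stat, k - 1, N - k, lower.tail = FALSE)
  }
  list(route = if (p < alpha) "nonparametric" else "parametric",
       statistic = unname(stat), df = c(k - 1, N - k), p = unname(p))
}

# covariate design matrix: numeric columns as-is; sex -> binary indicator;
# other character/factor columns one-hot with the largest level as reference
covariate_matrix <- function(covariates) {
  if (is.null(covariates) || !length(covariates)) return(NULL)
  cols <- list()
  for (nm in names(covariates)) {
    v <- covariates[[nm]]
    if (is.numeric(v)) {
      cols[[nm]] <- as.numeric(v)
    } else {
      f <- factor(v)
      if (nlevels(f) < 2) next  # constant covariate carries no information
      ref <- names(sort(table(f), decreasing = TRUE))[1]
      f <- relevel(f, ref)
      mm <- model.matrix(~f)[, -1, drop = FALSE]
      colnames(mm) <- paste0(nm, levels(f)[-1])
      for (j in seq_len(ncol(mm))) cols[[colnames(mm)[j]]] <- mm[, j]
    }
  }
  if (!length(cols)) return(NULL)
  do.call(cbind, cols)
}

#' ANCOVA omnibus group test with covariate-adjusted pairwise contrasts
#'
#' Omnibus Group F via nested linear-model comparison (covariates-only vs
#' covariates + Group); partial eta squared = SS_group / (SS_group +
#' SS_resid). Pairwise contrasts use covariate-adjusted group means with
#' pooled residual variance; the reported contrast df follows the printed
#' convention `n_i + n_j - 2` by default (`contrast_df = "pair"`), with the
#' adjusted-model residual df behind `contrast_df = "model"`.
#'
#' @param values numeric outcome.
#' @param group factor/character (>= 2 levels).
#' @param covariates data.frame of covariates (e.g. age, sex, site) or NULL.
#' @param contrast_df "pair" or "model".
#' @return list of class `group_test_result`: route, F, df, MSe, eta2p, p,
#'   and a data.frame `pairwise` (groups, estimate, t, df, p).
#' @export
ancova_group <- function(values, group, covariates = NULL,
                         contrast_df = c("pair", "model")) {
  contrast_df <- match.arg(contrast_df)
  group <- factor(group)
  if (nlevels(group) < 2) abort_stat("ancova_group: need >= 2 groups")
  n <- length(values)
  C <- covariate_matrix(covariates)
  X0 <- cbind(`(Intercept)` = rep(1, n), C)
  G <- model.matrix(~group)[, -1, drop = FALSE]
  X1 <- cbind(X0, G)
  q1 <- qr(X1)
  if (q1$rank < ncol(X1)) {
    aliased <- colnames(X1)[q1$pivot[(q1$rank + 1):ncol(X1)]]
    abort_stat(sprintf("ancova_group: design matrix rank deficient; aliased columns: %s",
                       paste(aliased, collapse = ", ")))
  }
  fit0 <- lm.fit(X0, values)
  fit1 <- lm.fit(X1, values)
  rss0 <- sum(fit0$residuals^2); rss1 <- sum(fit1$residuals^2)
  df_g <- nlevels(group) - 1
  df_r <- n - ncol(X1)
  if (df_r < 1) abort_stat("ancova_group: no residual degrees of freedom")
  Fv <- ((rss0 - rss1) / df_g) / (rss1 / df_r)
  p <- pf(Fv, df_g, df_r, lower.tail = FALSE)
  eta2p <- (rss0 - rss1) / (rss0 - rss1 + rss1)
  mse <- rss1 / df_r
  # pairwise covariate-adjusted contrasts
  XtXinv <- chol2inv(chol(crossprod(X1)))
  beta <- fit1$coefficients
  lv <- levels(group)
  pw <- list()
  for (a in seq_len(length(lv) - 1)) for (b in (a + 1):length(lv)) {
    cv <- rep(0, ncol(X1)); names(cv) <- colnames(X1)
    ca <- paste0("group", lv[a]); cb <- paste0("group", lv[b])
    if (ca %in% names(cv)) cv[ca] <- 1
    if (cb %in% names(cv)) cv[cb] <- -1
    est <- sum(cv * beta)
    se <- sqrt(mse * as.numeric(t(cv) %*% XtXinv %*% cv))
    dfc <- if (contrast_df == "pair") sum(group == lv[a]) + sum(group == lv[b]) - 2 else df_r
    tv <- est / se
    pw[[length(pw) + 1L]] <- data.frame(
      group1 = lv[a], group2 = lv[b], estimate = est, se = se,
      t = tv, df = dfc, p = 2 * pt(-abs(tv), dfc), stringsAsFactors = FALSE)
  }
  structure(list(route = "parametric", statistic = Fv, df = c(df_g, df_r),
                 MSe = mse, eta2p = eta2p, p = p,
                 pairwise = do.call(rbind, pw)),
            class = "group_test_result")
}

#' Kruskal-Wallis omnibus with Dunn pairwise z tests
#'
#' H uses the tie correction; Dunn z statistics compare mean ranks with the
#' tie-corrected pooled variance; pairwise p two-sided normal.
#'
#' @param values numeric outcome.
#' @param group factor/character.
#' @return a `group_test_result`: route, H (statistic), df, p, pairwise
#'   (groups, z, p).
#' @export
kruskal_dunn <- function(values, group) {
  group <- factor(group)
  if (nlevels(group) < 2) abort_stat("kruskal_dunn: need >= 2 groups")
  N <- length(values)
  r <- rank(values)
  ng <- table(group)
  Rg <- tapply(r, group, sum)
  ties <- table(values)
  TIE <- sum(ties^3 - ties)
  H_raw <- 12 / (N * (N + 1)) * sum(Rg^2 / ng) - 3 * (N + 1)
  ctie <- 1 - TIE / (N^3 - N)
  H <- if (ctie > 0) H_raw / ctie else 0
  df <- nlevels(group) - 1
  p <- if (ctie > 0) pchisq(H, df, lower.tail = FALSE) else 1
  if (ctie <= 0) H <- 0   # all values tied across all groups
  rbar <- Rg / ng
  sig2 <- N * (N + 1) / 12 - TIE / (12 * (N - 1))
  lv <- levels(group)
  pw <- list()
  for (a in seq_len(length(lv) - 1)) for (b in (a + 1):length(lv)) {
    se <- sqrt(sig2 * (1 / ng[[a]] + 1 / ng[[b]]))
    z <- if (se > 0) (rbar[[a]] - rbar[[b]]) / se else 0
    pw[[length(pw) + 1L]] <- data.frame(group1 = lv[a], group2 = lv[b], z = z,
                                        p = 2 * pnorm(-abs(z)), stringsAsFactors = FALSE)
  }
  structure(list(route = "nonparametric", statistic = unname(H), df = df, p = unname(p),
                 pairwise = do.call(rbind, pw)),
            class = "group_test_result")
}

#' Family-wise p-value adjustment
#'
#' Bonferroni (`min(1, p * m)`) or Benjamini-Hochberg step-up with enforced
#' monotonicity. The family size `m` defaults to the number of p-values but
#' can be fixed (e.g. 96 for the full feature grid, the battery's default
#' family) — `m` may exceed `length(p)`, which is conservative.
#'
#' @param p numeric p-values in `[0, 1]`.
#' @param method "bonferroni" or "benjamini-hochberg" (alias "BH").
#' @param family_size m; defaults to `length(p)`.
#' @return adjusted p-values, same order as input.
#' @export
adjust_pvalues <- function(p, method = c("bonferroni", "benjamini-hochberg", "BH"),
                           family_size = NULL) {
  method <- match.arg(method)
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort_stat("adjust_pvalues: p outside [0, 1]")
  m <- max(family_size %||% length(p), length(p))
  if (method == "bonferroni") return(pmin(1, p * m))
  ok <- !is.na(p)
  out <- rep(NA_real_, length(p))
  pp <- p[ok]
  o <- order(pp, decreasing = TRUE)
  ro <- order(o)
  i <- length(pp):1                           # ascending ranks of the descending sort
  out[ok] <- pmin(1, cummin(m / i * pp[o]))[ro]
  out
}

#' Bayesian equivalence test via BIC approximation
#'
#' BF10 for including Group (two levels) in an ANCOVA with the given
#' covariates, approximated as `exp((BIC_null - BIC_group) / 2)` where both
#' models contain the covariates. BF10 < 1 supports group equivalence. The
#' approximation method tag is recorded; a JZS-prior Bayes factor would
#' differ in magnitude but rarely in direction.
#'
#' @param values numeric outcome.
#' @param group two-level factor/character.
#' @param covariates data.frame (e.g. age, sex) or NULL.
#' @return list of class `equivalence_result`: BF10, method = "BIC",
#'   bic_null, bic_group, groups.
#' @export
bayes_equivalence <- function(values, group, covariates = NULL) {
  group <- factor(group)
  if (nlevels(group) != 2) abort_stat("bayes_equivalence: need exactly 2 groups")
  C <- covariate_matrix(covariates)
  ncov <- if (is.null(C)) 0 else ncol(C)
  if (length(values) < ncov + 3) abort_stat("bayes_equivalence: n too small for the design")
  dat <- data.frame(y = values, group = group)
  if (!is.null(C)) dat <- cbind(dat, as.data.frame(C))
  rhs0 <- if (ncov) paste(colnames(C), collapse = " + ") else "1"
  m0 <- lm(stats::as.formula(paste("y ~", rhs0)), dat)
  m1 <- lm(stats::as.formula(paste("y ~", rhs0, "+ group")), dat)
  b0 <- BIC(m0); b1 <- BIC(m1)
  structure(list(BF10 = exp((b0 - b1) / 2), method = "BIC",
                 bic_null = b0, bic_group = b1, groups = levels(group)),
            class = "equivalence_result")
}

# cached full permutation matrices for the exact Spearman null
.perm_cache <- new.env(parent = emptyenv())
all_perms <- function(n) {
  key <- as.character(n)
  if (!is.null(.perm_cache[[key]])) return(.perm_cache[[key]])
  P <- matrix(1L, 1, 1)
  if (n > 1) for (k in 2:n) {
    old <- P
    P <- matrix(0L, nrow(old) * k, k)
    at <- 0L
    for (pos in 1:k) {
      blk <- matrix(0L, nrow(old), k)
      if (pos > 1) blk[, 1:(pos - 1)] <- old[, 1:(pos - 1), drop = FALSE]
      blk[, pos] <- k
      if (pos < k) blk[, (pos + 1):k] <- old[, pos:(k - 1), drop = FALSE]
      P[at + seq_len(nrow(old)), ] <- blk
      at <- at + nrow(old)
    }
  }
  .perm_cache[[key]] <- P
  P
}

#' Spearman rank correlation with exact small-sample p
#'
#' Average-rank ties; two-sided p by exhaustive permutation enumeration for
#' n <= 9 with untied data, otherwise by the t approximation.
#'
#' @param x,y numeric vectors (pairs with missing values dropped).
#' @return list: r_s, p, n, method; or (r_s = NA, reason =) when n < 4 or a
#'   variable has zero variance.
#' @export
spearman_assoc <- function(x, y) {
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 4) return(list(r_s = NA_real_, p = NA_real_, n = n, reason = "n < 4"))
  if (sd(x) == 0 || sd(y) == 0)
    return(list(r_s = NA_real_, p = NA_real_, n = n, reason = "zero variance"))
  rx <- rank(x); ry <- rank(y)
  r_s <- suppressWarnings(stats::cor(rx, ry))
  no_ties <- !anyDuplicated(x) && !anyDuplicated(y)
  if (n <= 9 && no_ties) {
    P <- all_perms(n)
    base <- sort(ry)
    # r over all permutations of y-ranks against the fixed x-ranks
    xc <- rx - mean(rx)
    denom <- sqrt(sum(xc^2)) * sqrt(sum((base - mean(base))^2))
    num <- (matrix(base[P], nrow(P), n) - mean(base)) %*% xc
    rs_all <- as.numeric(num) / denom
    p <- mean(abs(rs_all) >= abs(r_s) - 1e-12)
    return(list(r_s = r_s, p = p, n = n, method = "exact"))
  }
  tv <- r_s * sqrt((n - 2) / (1 - r_s^2 + 1e-300))
  list(r_s = r_s, p = 2 * pt(-abs(tv), n - 2), n = n, method = "t")
}

#' Run the full Levene-gated battery over a feature table
#'
#' For each feature column: Levene gate, then ANCOVA (parametric route) or
#' Kruskal-Wallis + Dunn (non-parametric route); omnibus and pairwise
#' p-values corrected over the configured family.
#'
#' @param features data.frame with a `subject` column + numeric features.
#' @param cohort cohort table (matched by `subject`).
#' @param covariate_names covariate columns of the cohort used in the ANCOVA
#'   route; "site" is dropped automatically when it has a single level.
#' @param correction "bonferroni" or "benjamini-hochberg".
#' @param family_size Bonferroni family m (default 96, the full feature
#'   grid's family).
#' @param alpha significance threshold recorded in the report.
#' @param fast if TRUE, use the vectorised omnibus-only path (identical
#'   p-values, no pairwise table) — used by the large calibration runs.
#' @return list of class `battery_report`: `omnibus` (long data.frame),
#'   `pairwise` (NULL when fast), `family_size`, `correction`.
#' @export
run_group_battery <- function(features, cohort,
                              covariate_names = c("age", "sex"),
                              correction = "bonferroni", family_size = 96,
                              alpha = 0.05, fast = FALSE) {
  stopifnot("subject" %in% names(features))
  ord <- match(features$subject, cohort$subject)
  if (anyNA(ord)) abort_data("run_group_battery: feature subjects missing from cohort")
  coh <- cohort[ord, , drop = FALSE]
  covariate_names <- covariate_names[covariate_names %in% names(coh)]
  if ("site" %in% covariate_names && length(unique(coh$site)) < 2)
    covariate_names <- setdiff(covariate_names, "site")
  covs <- if (length(covariate_names)) coh[, covariate_names, drop = FALSE] else NULL
  fcols <- setdiff(names(features), "subject")
  group <- factor(coh$group)
  if (fast) return(battery_fast(features, fcols, group, covs, correction, family_size, alpha))
  om <- list(); pw <- list()
  for (fc in fcols) {
    y <- features[[fc]]
    ok <- !is.na(y)
    gtab <- table(group[ok])
    if (length(gtab) < 2 || any(gtab < 2)) {
      # feature unusable (e.g. empty bundles across a group): explicit NA row
      om[[fc]] <- data.frame(feature = fc, route = "skipped", statistic = NA_real_,
                             df1 = NA_real_, df2 = NA_real_, MSe = NA_real_,
                             eta2p = NA_real_, levene_p = NA_real_, p = NA_real_,
                             stringsAsFactors = FALSE)
      next
    }
    gate <- levene_gate(y[ok], group[ok])
    res <- if (gate$route == "parametric") {
      ancova_group(y[ok], group[ok], if (is.null(covs)) NULL else covs[ok, , drop = FALSE])
    } else kruskal_dunn(y[ok], group[ok])
    om[[fc]] <- data.frame(feature = fc, route = res$route,
                           statistic = res$statistic, df1 = res$df[1],
                           df2 = if (length(res$df) > 1) res$df[2] else NA_real_,
                           MSe = res$MSe %||% NA_real_, eta2p = res$eta2p %||% NA_real_,
                           levene_p = gate$p, p = res$p, stringsAsFactors = FALSE)
    pwd <- res$pairwise
    pwd$feature <- fc
    pw[[fc]] <- pwd
  }
  omnibus <- do.call(rbind, om); rownames(omnibus) <- NULL
  pairwise <- do.call(rbind, pw); rownames(pairwise) <- NULL
  omnibus$p_adj <- adjust_pvalues(omnibus$p, correction, family_size)
  pairwise$p_adj <- adjust_pvalues(pairwise$p, correction, family_size)
  structure(list(omnibus = omnibus, pairwise = pairwise,
                 family_size = max(family_size, length(fcols)),
                 correction = correction, alpha = alpha),
            class = "battery_report")
}

# vectorised omnibus-only battery (no NAs supported); p-values identical to
# the per-feature route
battery_fast <- function(features, fcols, group, covs, correction, family_size, alpha) {
  Y <- as.matrix(features[, fcols, drop = FALSE])
  n <- nrow(Y); k <- nlevels(group)
  gi <- as.integer(group)
  ng <- tabulate(gi, k)
  # Levene (Brown-Forsythe), vectorised over columns
  med <- apply(Y, 2, function(col) tapply(col, gi, median))  # k x p
  Z <- abs(Y - med[gi, , drop = FALSE])
  zbar_g <- rowsum(Z, gi) / ng
  zbar <- colMeans(Z)
  ssb <- colSums(ng * (zbar_g - matrix(zbar, k, length(fcols), byrow = TRUE))^2)
  ssw <- colSums((Z - zbar_g[gi, , drop = FALSE])^2)
  lev_F <- (ssb / (k - 1)) / (ssw / (n - k))
  lev_p <- ifelse(ssw == 0 & ssb == 0, 1,
                  ifelse(ssw == 0, 0, pf(lev_F, k - 1, n - k, lower.tail = FALSE)))
  route <- ifelse(lev_p < 0.05, "nonparametric", "parametric")
  C <- covariate_matrix(covs)
  X0 <- cbind(rep(1, n), C)
  X1 <- cbind(X0, model.matrix(~group)[, -1, drop = FALSE])
  Q0 <- qr.Q(qr(X0)); Q1 <- qr.Q(qr(X1))
  R0 <- Y - Q0 %*% crossprod(Q0, Y)
  R1 <- Y - Q1 %*% crossprod(Q1, Y)
  rss0 <- colSums(R0^2); rss1 <- colSums(R1^2)
  df_g <- k - 1; df_r <- n - ncol(X1)
  Fv <- ((rss0 - rss1) / df_g) / (rss1 / df_r)
  p <- pf(Fv, df_g, df_r, lower.tail = FALSE)
  stat <- Fv
  np <- which(route == "nonparametric")
  for (j in np) {
    kd <- kruskal_dunn(Y[, j], group)
    p[j] <- kd$p; stat[j] <- kd$statistic
  }
  omnibus <- data.frame(feature = fcols, route = route, statistic = stat,
                        df1 = df_g, df2 = ifelse(route == "parametric", df_r, NA_real_),
                        MSe = ifelse(route == "parametric", rss1 / df_r, NA_real_),
                        eta2p = ifelse(route == "parametric", (rss0 - rss1) / rss0, NA_real_),
                        levene_p = lev_p, p = p, stringsAsFactors = FALSE)
  omnibus$p_adj <- adjust_pvalues(omnibus$p, correction, family_size)
  rownames(omnibus) <- NULL
  structure(list(omnibus = omnibus, pairwise = NULL,
                 family_size = max(family_size, length(fcols)),
                 correction = correction, alpha = alpha),
            class = "battery_report")
}
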