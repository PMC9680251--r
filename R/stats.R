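## Cohort statistics relating perfusion parameters to lung shunt fraction
## (LSF): risk-group split at LSF 10%, Spearman correlation with F-based
## significance, Mann-Whitney U comparisons, ROC analysis with bootstrap
## CIs and Youden thresholds, and the paired DeLong AUC comparison.

#' Split a cohort into low- and high-risk LSF groups
#'
#' Low risk is LSF <= threshold (inclusive boundary), high risk is
#' LSF > threshold; the partition is exhaustive and disjoint.
#'
#' @param cohort data.frame with an `lsf_percent` column.
#' @param threshold_percent split point, default 10 (%).
#' @return list with `low` and `high` data.frames and `threshold_percent`.
#' @export
split_groups <- function(cohort, threshold_percent = 10) {
  if (!is.data.frame(cohort) || nrow(cohort) == 0L)
    stop("'cohort' must be a nonempty data.frame")
  if (is.null(cohort$lsf_percent)) stop("cohort lacks column 'lsf_percent'")
  low <- cohort[cohort$lsf_percent <= threshold_percent, , drop = FALSE]
  high <- cohort[cohort$lsf_percent > threshold_percent, , drop = FALSE]
  if (nrow(low) == 0L || nrow(high) == 0L)
    warning(sprintf("a group is empty (low n=%d, high n=%d): two-group statistics unavailable",
                    nrow(low), nrow(high)))
  list(low = low, high = high, threshold_percent = threshold_percent)
}

#' F-statistic for a correlation coefficient
#'
#' The regression F transform `F = (n - 2) * r^2 / (1 - r^2)`, referred to
#' F(1, n-2), used to attach significance to Spearman's rho.
#'
#' @param r correlation coefficient in [-1, 1].
#' @param n sample size (> 2).
#' @return F value (Inf at |r| = 1).
#' @export
spearman_f <- function(r, n) {
  if (any(abs(r) > 1) || n <= 2) stop("need |r| <= 1 and n > 2")
  ifelse(abs(r) >= 1, Inf, (n - 2) * r^2 / (1 - r^2))
}

#' Spearman correlation with F-statistic significance
#'
#' Spearman's rho (average ranks for ties) with significance through the
#' transform `F = (n-2) * r^2 / (1 - r^2)` referred to F(1, n-2) — the
#' construction whose F values match published perfusion/LSF correlation
#' tables — and a 95% CI by the Fisher z-transform. An exact permutation
#' p-value is available for small samples via `method = "permutation"`.
#'
#' @param x,y numeric vectors of equal length, n >= 4.
#' @param method "f" (default) or "permutation" (exact, n <= 8).
#' @return list of class `correlation_result`: `r`, `ci_low`, `ci_high`,
#'   `f_stat`, `p`, `n`.
#' @export
spearman_corr <- function(x, y, method = c("f", "permutation")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  n <- length(x)
  if (n < 4L) stop("need at least 4 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: Spearman correlation undefined")
  r <- stats::cor(x, y, method = "spearman")
  f_stat <- spearman_f(r, n)
  p <- if (method == "f") {
    max(stats::pf(f_stat, 1, n - 2, lower.tail = FALSE),
        .Machine$double.xmin)
  } else {
    if (n > 8L) stop("exact permutation p limited to n <= 8")
    perms <- permutations_of(n)
    ry <- rank(y)
    r_obs <- abs(r)
    r_perm <- apply(perms, 1, function(p_)
      stats::cor(rank(x), ry[p_]))
    max(mean(abs(r_perm) >= r_obs - 1e-12), .Machine$double.xmin)
  }
  z <- atanh(min(max(r, -1 + 1e-12), 1 - 1e-12))
  se <- 1 / sqrt(n - 3)
  ci <- tanh(z + c(-1, 1) * stats::qnorm(0.975) * se)
  structure(list(r = r, ci_low = ci[1], ci_high = ci[2], f_stat = f_stat,
                 p = p, n = n),
            class = "correlation_result")
}

permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Mann-Whitney U comparison of two groups
#'
#' U statistic with average-rank tie handling, oriented as the number of
#' (high, low) pairs in which the high-group value exceeds the low-group
#' value (ties half-credit), so that `U / (n1*n2)` equals the ROC AUC of
#' the grouping. The two-sided p-value is exact (distribution enumeration)
#' when `n1*n2 <= 400` and no ties are present, otherwise a normal
#' approximation with tie and continuity corrections. Group means and SDs
#' are returned for reporting.
#'
#' @param low,high numeric vectors, both nonempty.
#' @return list of class `group_comparison`: `mean_low`, `sd_low`,
#'   `mean_high`, `sd_high`, `u_stat`, `p`, `n_low`, `n_high`, `exact`.
#' @export
mann_whitney <- function(low, high) {
  if (length(low) == 0L || length(high) == 0L)
    stop("both groups must be nonempty")
  n1 <- length(low); n2 <- length(high)
  rk <- rank(c(high, low))
  u_high <- sum(rk[seq_len(n2)]) - n2 * (n2 + 1) / 2
  has_ties <- anyDuplicated(c(high, low)) > 0
  exact <- (n1 * n2 <= 400) && !has_ties
  wt <- suppressWarnings(
    stats::wilcox.test(high, low, exact = exact, correct = TRUE))
  structure(list(mean_low = mean(low), sd_low = stats::sd(low),
                 mean_high = mean(high), sd_high = stats::sd(high),
                 u_stat = u_high, p = min(wt$p.value, 1),
                 n_low = n1, n_high = n2, exact = exact),
            class = "group_comparison")
}

## Rank-formula AUC with half-credit for ties: probability that a random
## positive value exceeds a random negative one.
auc_rank <- function(values, labels) {
  pos <- values[labels]; neg <- values[!labels]
  rk <- rank(c(pos, neg))
  (sum(rk[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' ROC analysis with bootstrap CI and Youden threshold
#'
#' AUC by the rank (Mann-Whitney) formulation with half-credit for ties;
#' 95% CI by stratified bootstrap percentile (resampling positives and
#' negatives separately); the operating threshold maximizes
#' sensitivity + specificity (Youden), predicting high risk when the value
#' is at or above the threshold, with ties broken toward the lower
#' threshold. If the AUC falls below 0.5 the result is flagged (not
#' silently reoriented).
#'
#' @param values numeric predictor (higher = more likely high-risk).
#' @param labels logical (or 0/1) high-risk indicator; both classes must
#'   be present.
#' @param boot_n bootstrap resamples for the CI (default 2000).
#' @param seed integer seed for the bootstrap, or `NULL`.
#' @param conf confidence level (default 0.95).
#' @return list of class `roc_result`: `auc`, `ci_low`, `ci_high`,
#'   `sensitivity`, `specificity`, `threshold`, `curve` (data.frame),
#'   `flagged_low_auc`.
#' @export
roc_analysis <- function(values, labels, boot_n = 2000L, seed = NULL,
                         conf = 0.95) {
  labels <- as.logical(labels)
  if (length(values) != length(labels)) stop("length mismatch")
  if (any(is.na(values)) || any(is.na(labels))) stop("missing values")
  if (!any(labels) || all(labels))
    stop("both classes must be present for ROC analysis")
  auc <- auc_rank(values, labels)

  thresholds <- sort(unique(values))
  sens <- vapply(thresholds, function(th)
    mean(values[labels] >= th), numeric(1))
  spec <- vapply(thresholds, function(th)
    mean(values[!labels] < th), numeric(1))
  youden <- sens + spec
  best <- which(youden >= max(youden) - 1e-12)[1]  # lower threshold on ties
  curve <- data.frame(threshold = thresholds, sensitivity = sens,
                      specificity = spec)

  ipos <- which(labels); ineg <- which(!labels)
  boots <- with_seed(seed, vapply(seq_len(boot_n), function(i) {
    bi <- c(ipos[sample.int(length(ipos), replace = TRUE)],
            ineg[sample.int(length(ineg), replace = TRUE)])
    auc_rank(values[bi], labels[bi])
  }, numeric(1)))
  alpha <- (1 - conf) / 2
  ci <- stats::quantile(boots, c(alpha, 1 - alpha), names = FALSE,
                        type = 6)
  ci[1] <- min(ci[1], auc); ci[2] <- max(ci[2], auc)
  structure(list(auc = auc, ci_low = ci[1], ci_high = ci[2],
                 sensitivity = sens[best], specificity = spec[best],
                 threshold = thresholds[best], curve = curve,
                 flagged_low_auc = auc < 0.5),
            class = "roc_result")
}

#' Paired DeLong test comparing two AUCs
#'
#' Two-sided DeLong test for the difference between the AUCs of two
#' predictors measured on the same subjects, using the structural
#' components (placement values) of each AUC to estimate the variance of
#' the paired difference.
#'
#' @param values1,values2 paired numeric predictors.
#' @param labels logical high-risk indicator; at least two subjects per
#'   class.
#' @return list: `p`, `auc1`, `auc2`, `z`.
#' @export
compare_auc <- function(values1, values2, labels) {
  labels <- as.logical(labels)
  if (length(values1) != length(values2) ||
      length(values1) != length(labels))
    stop("predictors and labels must have equal length")
  m <- sum(labels); n <- sum(!labels)
  if (m < 2L || n < 2L)
    stop("DeLong comparison needs at least two subjects per class")
  psi <- function(x, y) (x > y) + 0.5 * (x == y)
  comp <- function(v) {
    pos <- v[labels]; neg <- v[!labels]
    mat <- outer(pos, neg, psi)
    list(auc = mean(mat), v10 = rowMeans(mat), v01 = colMeans(mat))
  }
  c1 <- comp(values1); c2 <- comp(values2)
  s10 <- stats::cov(cbind(c1$v10, c2$v10))
  s01 <- stats::cov(cbind(c1$v01, c2$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  d <- c1$auc - c2$auc
  if (var_diff <= 0) {
    z <- 0
    p <- 1
  } else {
    z <- d / sqrt(var_diff)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(p = p, auc1 = c1$auc, auc2 = c2$auc, z = z)
}

COHORT_PARAMS <- c(roi_speed = "QTM |u|", roi_ktrans = "Ktrans",
                   roi_ve = "Ve", roi_tau = "tau",
                   tumor_volume_cm3 = "Tumor volume", age = "Age")
PERFUSION_PARAMS <- c("roi_speed", "roi_ktrans", "roi_ve", "roi_tau")

#' Cohort report: correlation, ROC and group-comparison tables
#'
#' Runs the full statistics stage on a cohort table: Spearman correlation
#' of each of the six parameters (QTM speed, Ktrans, Ve, tau, tumor
#' volume, age) with LSF; ROC analysis of each parameter for the
#' low/high-risk split at LSF 10%; and Mann-Whitney comparisons of the
#' four perfusion parameters between risk groups.
#'
#' @param cohort data.frame with columns `lsf_percent`, `roi_speed`,
#'   `roi_ktrans`, `roi_ve`, `roi_tau`, `tumor_volume_cm3`, `age`.
#' @param threshold_percent LSF risk split (default 10).
#' @param boot_n bootstrap resamples for ROC CIs.
#' @param seed bootstrap seed.
#' @return list of class `cohort_report`: `correlations` and `roc`
#'   (data.frames, one row per parameter), `groups` (data.frame, one row
#'   per perfusion parameter), `split` (group sizes).
#' @export
build_report <- function(cohort, threshold_percent = 10, boot_n = 2000L,
                         seed = 1L) {
  needed <- c("lsf_percent", names(COHORT_PARAMS))
  missing_cols <- setdiff(needed, names(cohort))
  if (length(missing_cols) > 0L)
    stop(sprintf("cohort is missing column(s): %s",
                 paste(missing_cols, collapse = ", ")))
  grp <- split_groups(cohort, threshold_percent)
  labels <- cohort$lsf_percent > threshold_percent

  correlations <- do.call(rbind, lapply(names(COHORT_PARAMS), function(par) {
    ## a degenerate (zero-variance) parameter yields an NA row rather than
    ## aborting the remaining parameters
    ct <- tryCatch(spearman_corr(cohort[[par]], cohort$lsf_percent),
                   error = function(e) list(r = NA_real_, ci_low = NA_real_,
                                            ci_high = NA_real_,
                                            f_stat = NA_real_, p = NA_real_))
    data.frame(parameter = COHORT_PARAMS[[par]], column = par, r = ct$r,
               ci_low = ct$ci_low, ci_high = ct$ci_high,
               f_value = ct$f_stat, p = ct$p)
  }))
  roc <- do.call(rbind, lapply(seq_along(COHORT_PARAMS), function(i) {
    par <- names(COHORT_PARAMS)[i]
    rr <- roc_analysis(cohort[[par]], labels, boot_n = boot_n,
                       seed = seed + i)
    data.frame(parameter = COHORT_PARAMS[[par]], column = par,
               auc = rr$auc, ci_low = rr$ci_low, ci_high = rr$ci_high,
               sensitivity = rr$sensitivity, specificity = rr$specificity,
               threshold = rr$threshold, flagged_low_auc = rr$flagged_low_auc)
  }))
  groups <- do.call(rbind, lapply(PERFUSION_PARAMS, function(par) {
    mw <- mann_whitney(grp$low[[par]], grp$high[[par]])
    data.frame(parameter = COHORT_PARAMS[[par]], column = par,
               mean_low = mw$mean_low, sd_low = mw$sd_low,
               mean_high = mw$mean_high, sd_high = mw$sd_high,
               u_stat = mw$u_stat, p = mw$p)
  }))
  rownames(correlations) <- rownames(roc) <- rownames(groups) <- NULL
  structure(list(correlations = correlations, roc = roc, groups = groups,
                 split = c(low = nrow(grp$low), high = nrow(grp$high)),
                 threshold_percent = threshold_percent),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("Cohort report (LSF split at %g%%: %d low / %d high)\n\n",
              x$threshold_percent, x$split["low"], x$split["high"]))
  cat("Spearman correlation with LSF:\n")
  print(format(x$correlations[, c("parameter", "r", "f_value", "p")],
               digits = 4), row.names = FALSE)
  cat("\nROC (high-risk classification):\n")
  print(format(x$roc[, c("parameter", "auc", "ci_low", "ci_high",
                         "sensitivity", "specificity")], digits = 3),
        row.names = FALSE)
  cat("\nGroup comparison (Mann-Whitney):\n")
  print(format(x$groups, digits = 3), row.names = FALSE)
  invisible(x)
}

#' Write the report tables as CSV
#'
#' Writes `table1.csv` (correlations), `table2.csv` (ROC), `groups.csv`
#' (Mann-Whitney) and `summary.json` into a directory.
#'
#' @param report a [build_report()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(report$correlations, file.path(dir, "table1.csv"),
                   row.names = FALSE)
  utils::write.csv(report$roc, file.path(dir, "table2.csv"),
                   row.names = FALSE)
  utils::write.csv(report$groups, file.path(dir, "groups.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(split = as.list(report$split),
         threshold_percent = report$threshold_percent,
         top_by_r = report$correlations$column[which.max(abs(report$correlations$r))],
         top_by_auc = report$roc$column[which.max(report$roc$auc)]),
    file.path(dir, "summary.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
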