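# Cohort statistics: group split, Spearman/F, Mann-Whitney, ROC, DeLong.

test_that("LSF split is inclusive at the threshold and exhaustive", {
  co <- data.frame(lsf_percent = c(9.3, 15.3))
  sp <- split_groups(co)
  expect_equal(c(nrow(sp$low), nrow(sp$high)), c(1L, 1L))

  co2 <- data.frame(lsf_percent = c(10, 10.0001, 3))
  sp2 <- split_groups(co2)
  expect_equal(nrow(sp2$low), 2L)   # boundary value goes low

  expect_warning(split_groups(data.frame(lsf_percent = rep(5, 4))),
                 "empty")
})

test_that("Spearman r, F transform and CI behave as specified", {
  x <- 1:8
  expect_equal(spearman_corr(x, 2 * x + 3)$r, 1)
  expect_equal(spearman_corr(x, 2 * x + 3)$f_stat, Inf)

  # brute-force rank-formula oracle on tie-free 6-point data
  set.seed(14)
  for (k in 1:5) {
    xx <- sample(100, 6); yy <- sample(100, 6)
    d <- rank(xx) - rank(yy)
    r_oracle <- 1 - 6 * sum(d^2) / (6 * (36 - 1))
    out <- spearman_corr(xx, yy)
    expect_equal(out$r, r_oracle, tolerance = 1e-12)
    expect_equal(out$f_stat, (6 - 2) * out$r^2 / (1 - out$r^2),
                 tolerance = 1e-12)
    expect_true(out$ci_low <= out$r & out$r <= out$ci_high)
  }

  # invariance under strictly monotone transforms
  set.seed(15)
  xx <- runif(12); yy <- runif(12)
  expect_equal(spearman_corr(exp(xx), yy^3)$r, spearman_corr(xx, yy)$r)

  expect_error(spearman_corr(rep(1, 6), 1:6), "variance")
  expect_error(spearman_corr(1:3, 1:3), "at least 4")
})

test_that("Mann-Whitney: symmetry, the 3-vs-3 textbook case, and U range", {
  a <- c(1, 2, 3, 4)
  mw_eq <- mann_whitney(a, a)
  expect_equal(mw_eq$u_stat, length(a)^2 / 2)
  expect_gt(mw_eq$p, 0.9)

  mw <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$u_stat, 9)        # all high > all low
  expect_equal(mw$p, 0.1)           # two-sided exact 2 * 1/20
  expect_true(mw$exact)

  expect_error(mann_whitney(numeric(0), 1:3), "nonempty")
})

test_that("exact Mann-Whitney p equals brute-force enumeration (n1 = n2 = 4)", {
  set.seed(33)
  for (k in 1:6) {
    vals <- sample(1000, 8)          # integers, tie-free
    a <- vals[1:4]; b <- vals[5:8]
    mw <- mann_whitney(a, b)
    # enumerate all C(8,4) assignments of the pooled values to the groups
    pooled <- c(a, b)
    u_of <- function(idx_b) {
      bb <- pooled[idx_b]; aa <- pooled[-idx_b]
      sum(outer(bb, aa, ">"))
    }
    u_all <- apply(combn(8, 4), 2, u_of)
    u_obs <- mw$u_stat
    # two-sided: double the smaller tail (distribution is symmetric)
    p_oracle <- min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
    expect_equal(mw$p, p_oracle, tolerance = 1e-12)
  }
})

test_that("ROC: separation, ties, and the AUC-U identity", {
  r <- roc_analysis(c(1, 2, 3, 10, 11, 12), c(F, F, F, T, T, T),
                    boot_n = 200, seed = 1)
  expect_equal(r$auc, 1)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)
  expect_true(r$threshold %in% c(10))  # lowest maximizing threshold

  r_tie <- roc_analysis(rep(2, 6), c(F, F, F, T, T, T), boot_n = 50,
                        seed = 1)
  expect_equal(r_tie$auc, 0.5)

  set.seed(44)
  for (k in 1:5) {
    v <- sample(1000, 12)
    lab <- rep(c(TRUE, FALSE), each = 6)
    r2 <- roc_analysis(v, lab, boot_n = 100, seed = k)
    mw <- mann_whitney(v[!lab], v[lab])
    expect_equal(r2$auc * 36, mw$u_stat)
    expect_equal(r2$auc, oracle_auc(v, lab))
    expect_true(r2$ci_low <= r2$auc & r2$auc <= r2$ci_high)
    expect_true(r2$threshold %in% v)
  }

  r_flip <- roc_analysis(c(5, 4, 3, 2, 1, 0), c(T, T, T, F, F, F) == FALSE,
                         boot_n = 50, seed = 2)
  expect_true(r_flip$flagged_low_auc)
  expect_error(roc_analysis(1:4, c(TRUE, TRUE, TRUE, TRUE)), "classes")
})

test_that("bootstrap ROC confidence intervals are seeded and reproducible", {
  set.seed(50)
  v <- rnorm(30) + rep(c(0, 1), each = 15)
  lab <- rep(c(FALSE, TRUE), each = 15)
  r1 <- roc_analysis(v, lab, boot_n = 500, seed = 7)
  r2 <- roc_analysis(v, lab, boot_n = 500, seed = 7)
  expect_identical(r1$ci_low, r2$ci_low)
  expect_lt(r1$ci_low, r1$auc)
})

test_that("DeLong: self-comparison, degenerate input, permutation agreement", {
  lab <- rep(c(TRUE, FALSE), each = 10)
  set.seed(42)
  v <- rnorm(20) + lab
  expect_equal(compare_auc(v, v, lab)$p, 1)
  expect_error(compare_auc(1:2, 2:1, c(TRUE, FALSE)), "two subjects")

  for (s in c(42, 1, 7)) {
    set.seed(s)
    v1 <- rnorm(20) + lab * 1.2
    v2 <- rnorm(20) + lab * 0.6
    dl <- compare_auc(v1, v2, lab)
    obs <- oracle_auc(v1, lab) - oracle_auc(v2, lab)
    set.seed(99)
    perm <- replicate(1e4, {
      pl <- sample(lab)
      oracle_auc(v1, pl) - oracle_auc(v2, pl)
    })
    p_perm <- mean(abs(perm) >= abs(obs) - 1e-12)
    # asymptotic z-test vs exact resampling at n = 20: small-sample band
    expect_lt(abs(dl$p - p_perm), 0.06)
  }
})

test_that("build_report emits six correlation and six ROC rows, deterministically", {
  co <- generate_cohort(25, seed = 77)
  rep1 <- build_report(co, boot_n = 200, seed = 5)
  rep2 <- build_report(co, boot_n = 200, seed = 5)
  expect_equal(nrow(rep1$correlations), 6L)
  expect_equal(nrow(rep1$roc), 6L)
  expect_equal(nrow(rep1$groups), 4L)
  expect_identical(rep1$roc, rep2$roc)
  expect_error(build_report(co[, setdiff(names(co), "roi_ve")]), "roi_ve")

  d <- tempfile()
  write_report(rep1, d)
  expect_true(all(file.exists(file.path(d, c("table1.csv", "table2.csv",
                                             "groups.csv", "summary.json")))))
  unlink(d, recursive = TRUE)
})
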