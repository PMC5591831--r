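test_that("pooled t-test matches textbook hand computations", {
  # identical samples: t = 0, p = 1
  res0 <- two_sample_ttest_equal_var(c(1, 2, 3), c(1, 2, 3))
  expect_equal(res0$t, 0, tolerance = 1e-12)
  expect_equal(res0$p, 1, tolerance = 1e-12)
  # pooled variance 1, difference -1: t = -1/sqrt(2/3)
  res <- two_sample_ttest_equal_var(c(1, 2, 3), c(2, 3, 4))
  expect_equal(res$t, -1.224745, tolerance = 1e-6)
  expect_identical(res$df, 4)
  # swapping samples negates t, p unchanged
  swp <- two_sample_ttest_equal_var(c(2, 3, 4), c(1, 2, 3))
  expect_equal(swp$t, -res$t, tolerance = 1e-12)
  expect_equal(swp$p, res$p, tolerance = 1e-12)
  expect_error(two_sample_ttest_equal_var(c(1, 1), c(1, 1)),
               "pooled variance")
  expect_error(two_sample_ttest_equal_var(1, c(1, 2)), ">= 2")
})

test_that("paired t-test matches hand computation on differences", {
  # differences (1, 2, 3): mean 2, sd 1, t = 2 / (1/sqrt(3))
  res <- paired_ttest(c(2, 4, 6), c(1, 2, 3))
  expect_equal(res$t, 3.464102, tolerance = 1e-6)
  expect_identical(res$df, 2)
  # sign flip of all differences negates t
  res2 <- paired_ttest(c(1, 2, 3), c(2, 4, 6))
  expect_equal(res2$t, -res$t, tolerance = 1e-12)
  # zero-variance differences are an explicit failure
  expect_error(paired_ttest(c(1, 2, 3), c(2, 3, 4)), "zero-variance")
  expect_error(paired_ttest(c(1, 2), c(1, 2, 3)), "equal length")
})

test_that("BH step-up matches hand examples and brute force", {
  r1 <- fdr_bh(c(0.01, 0.02, 0.03, 0.04), 0.05)
  expect_true(all(r1$mask))
  expect_equal(r1$p_threshold, 0.04)
  r2 <- fdr_bh(c(0.04, 0.05, 0.9), 0.05)
  expect_false(any(r2$mask))
  expect_true(is.na(r2$p_threshold))
  r3 <- fdr_bh(rep(1e-6, 7), 0.05)
  expect_true(all(r3$mask))
  empty <- fdr_bh(numeric(0), 0.05)
  expect_length(empty$mask, 0)
  set.seed(17)
  for (rep in 1:300) {
    m <- sample(1:40, 1)
    p <- runif(m)^sample(1:3, 1)   # mix of null-ish and signal-ish vectors
    q <- runif(1, 0.01, 0.2)
    expect_identical(fdr_bh(p, q)$mask, brute_bh(p, q))
  }
  expect_error(fdr_bh(c(0.5, 1.2), 0.05), "\\[0, 1\\]")
})

test_that("effect sizes reproduce the published regional table", {
  tab <- reference_region_table()
  # recomputation from the printed group summaries agrees with the printed
  # d and effect r within one unit of the second decimal on every row (a few
  # rows differ by exactly 0.01, consistent with rounding of the summaries)
  for (i in seq_len(nrow(tab))) {
    d <- cohens_d_pooled(tab$r1_gamma_mean[i], tab$r1_gamma_sd[i],
                         tab$r2_gamma_mean[i], tab$r2_gamma_sd[i])
    expect_lte(abs(round(d, 2) - tab$cohens_d[i]), 0.011)
    expect_lte(abs(round(effect_size_r(d), 2) - tab$effect_size[i]), 0.011)
  }
  expect_equal(cohens_d_pooled(1, 0.5, 1, 0.7), 0)
  expect_error(cohens_d_pooled(1, 0, 2, 1), "positive")
})

test_that("effect-size r is monotone, bounded and matches closed forms", {
  expect_equal(effect_size_r(0), 0)
  expect_equal(effect_size_r(2), sqrt(0.5), tolerance = 1e-12)
  d <- seq(-6, 6, by = 0.25)
  r <- effect_size_r(d)
  expect_true(all(diff(r) > 0))
  expect_true(all(abs(r) < 1))
  expect_error(effect_size_r(Inf), "finite")
})

test_that("sparsity ranges format in percent notation", {
  grid <- sparsity_grid()
  expect_identical(format_sparsity_ranges(c(0.11, 0.12, 0.13), grid),
                   "11%-13%")
  expect_identical(
    format_sparsity_ranges(c(seq(0.11, 0.17, 0.01), seq(0.20, 0.24, 0.01)),
                           grid),
    "11%-17%, 20%-24%")
  expect_identical(format_sparsity_ranges(0.29, grid), "29%")
  expect_identical(format_sparsity_ranges(numeric(0), grid), "")
})

make_curve_df <- function(n_per_group, groups, grid, shift_by_group,
                          seed, metric = "gamma") {
  set.seed(seed)
  out <- list()
  for (g in groups) {
    for (s in seq_len(n_per_group)) {
      subject <- sprintf("%s%02d", if (g == "HC") "H" else "P", s)
      out[[length(out) + 1]] <- data.frame(
        subject_id = subject, group = g, modality = "eeg", band = "beta2",
        sparsity = grid, metric = metric,
        value = 1 + shift_by_group[[g]] + rnorm(length(grid), sd = 0.1),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

test_that("curve comparison tests each level and reports contiguous ranges", {
  grid <- sparsity_grid()
  shifted <- make_curve_df(14, c("R1", "R2"), grid,
                           list(R1 = 0, R2 = 0.6), seed = 1)
  cmp <- compare_metric_curves(shifted, "gamma", "R1_vs_R2")
  expect_identical(nrow(cmp$table), 35L)
  expect_true(cmp$paired)
  expect_true(all(cmp$table$fdr_significant))
  expect_identical(cmp$significant_ranges, "11%-45%")
  expect_true(all(cmp$table$t_stat < 0))   # R2 above R1
  # identical group data: no significance anywhere
  null_df <- make_curve_df(10, c("HC", "R1"), grid,
                           list(HC = 0, R1 = 0), seed = 2)
  cmp0 <- compare_metric_curves(null_df, "gamma", "HC_vs_R1")
  expect_false(cmp0$paired)
  expect_identical(cmp0$significant_ranges, "")
  expect_error(compare_metric_curves(null_df, "gamma", "R2_vs_HC"),
               "unknown contrast")
})

test_that("node-level comparison finds planted nodes and keeps the schema", {
  set.seed(6)
  nodes <- sprintf("N%02d", 1:12)
  n_sub <- 14
  base <- matrix(rnorm(n_sub * 12, mean = 1.5, sd = 0.2), n_sub,
                 dimnames = list(sprintf("P%02d", 1:n_sub), nodes))
  boosted <- base + matrix(rnorm(n_sub * 12, sd = 0.05), n_sub)
  boosted[, "N03"] <- boosted[, "N03"] + 0.5          # planted node effect
  node_table <- data.frame(label = nodes, x_mm = 1:12, y_mm = 0, z_mm = 0)
  cmp <- node_level_comparison(list(R1 = base, R2 = boosted), "R1_vs_R2",
                               node_table = node_table)
  expect_true("N03" %in% cmp$significant_nodes)
  expect_identical(nrow(cmp$table), 12L)
  expect_true(all(c("region", "x_mm", "y_mm", "z_mm", "mean_R1", "sd_R1",
                    "mean_R2", "sd_R2", "t_stat", "p_value", "cohens_d",
                    "effect_r", "p_adjusted", "fdr_significant")
                  %in% names(cmp$table)))
  # output is sorted by p, so the planted node comes first
  expect_identical(cmp$table$region[1], "N03")
  # sign convention: boost in R2 gives positive d
  expect_gt(cmp$table$cohens_d[1], 0)
})
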