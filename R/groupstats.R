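# Per-sparsity and per-node group inference: pooled and paired t-tests,
# Benjamini-Hochberg FDR, Cohen's d (equal-n pooled form) and effect-size r.

#' Two-sample equal-variance t-test
#'
#' Pooled-variance t with `df = n1 + n2 - 2` and a two-sided p-value
#' (delegates to [stats::t.test()] with `var.equal = TRUE`).
#'
#' @param x,y numeric samples (each of length >= 2).
#' @return list with `t`, `p`, `df`.
#' @export
two_sample_ttest_equal_var <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) stop("each sample needs >= 2 values")
  pooled_var <- ((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
    (length(x) + length(y) - 2)
  if (pooled_var <= 0) stop("zero pooled variance: t undefined")
  ht <- t.test(x, y, var.equal = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value, df = unname(ht$parameter))
}

#' Paired two-sample t-test
#'
#' One-sample t on the paired differences, `df = n - 1`, two-sided p. The
#' caller guarantees pairing order (e.g., via the study manifest).
#'
#' @param x,y numeric samples of equal length, paired by position.
#' @return list with `t`, `p`, `df`.
#' @export
paired_ttest <- function(x, y) {
  if (length(x) != length(y)) stop("paired samples must have equal length")
  if (length(x) < 2) stop("need at least 2 pairs")
  if (sd(x - y) == 0) stop("zero-variance differences: paired t undefined")
  ht <- t.test(x, y, paired = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value, df = unname(ht$parameter))
}

#' Benjamini-Hochberg FDR step-up
#'
#' Returns the rejection mask at level `q` together with the data-dependent
#' p threshold (the largest p among rejected hypotheses) — the quantity
#' reported in papers as "FDR corrected p < ...".
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @param q FDR level in (0, 1).
#' @return list with `mask` (logical), `p_threshold` (largest rejected p, or
#'   `NA` if none) and `p_adjusted`.
#' @export
fdr_bh <- function(p_values, q = 0.05) {
  if (length(p_values) == 0) {
    return(list(mask = logical(0), p_threshold = NA_real_,
                p_adjusted = numeric(0)))
  }
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  if (!(q > 0 && q < 1)) stop("q must lie in (0, 1)")
  adj <- p.adjust(p_values, method = "BH")
  mask <- !is.na(adj) & adj <= q
  list(mask = mask,
       p_threshold = if (any(mask)) max(p_values[mask]) else NA_real_,
       p_adjusted = adj)
}

#' Cohen's d from group summaries (equal-n pooled SD)
#'
#' `d = (mean2 - mean1) / sqrt((sd1^2 + sd2^2) / 2)`. The sign follows the
#' direction of change from group 1 to group 2 (e.g., R1 to R2).
#'
#' @param mean1,sd1 first-group summary (e.g., R1).
#' @param mean2,sd2 second-group summary (e.g., R2).
#' @return Cohen's d.
#' @export
cohens_d_pooled <- function(mean1, sd1, mean2, sd2) {
  if (any(c(sd1, sd2) <= 0)) stop("standard deviations must be positive")
  (mean2 - mean1) / sqrt((sd1^2 + sd2^2) / 2)
}

#' Effect-size r from Cohen's d
#'
#' `r = d / sqrt(d^2 + 4)`; strictly increasing in d and bounded in (-1, 1).
#'
#' @param d Cohen's d (finite).
#' @return effect-size r.
#' @export
effect_size_r <- function(d) {
  if (any(!is.finite(d))) stop("d must be finite")
  d / sqrt(d^2 + 4)
}

contrast_groups <- function(contrast) {
  switch(contrast,
         HC_vs_R1 = c("HC", "R1"),
         HC_vs_R2 = c("HC", "R2"),
         R1_vs_R2 = c("R1", "R2"),
         stop("unknown contrast: ", contrast))
}

#' Format significant sparsity levels as contiguous percent ranges
#'
#' E.g., levels `c(0.11, 0.12, 0.13, 0.20)` become `"11%-13%, 20%"`.
#'
#' @param sig_levels sparsity levels flagged significant.
#' @param grid the full grid (defines contiguity).
#' @return a single string ("" when empty).
#' @export
format_sparsity_ranges <- function(sig_levels, grid = sparsity_grid()) {
  if (length(sig_levels) == 0) return("")
  idx <- sort(match(round(sig_levels, 10), round(grid, 10)))
  if (any(is.na(idx))) stop("significant level not on the grid")
  runs <- split(idx, cumsum(c(1, diff(idx) != 1)))
  pct <- function(i) sprintf("%g%%", 100 * grid[i])
  paste(vapply(runs, function(r) {
    if (length(r) == 1) pct(r[1]) else paste0(pct(r[1]), "-", pct(r[length(r)]))
  }, character(1)), collapse = ", ")
}

#' Compare metric curves between two groups across the sparsity grid
#'
#' One test per sparsity level (pooled two-sample t for HC contrasts, paired
#' t for R1 vs R2 with pairing by subject), BH-FDR across the levels, group
#' summaries, Cohen's d of the summaries and effect-size r. Significant
#' levels are also reported as contiguous percent ranges.
#'
#' @param curves long-format data.frame as produced by [curve_long()]
#'   (columns subject_id, group, sparsity, metric, value; optionally
#'   modality/band already filtered).
#' @param metric which metric to test (e.g., `"gamma"`).
#' @param contrast `"HC_vs_R1"`, `"HC_vs_R2"` or `"R1_vs_R2"` (paired).
#' @param q FDR level (default 0.05).
#' @return an object of class `mm_group_comparison`: `table` (one row per
#'   sparsity: means, SDs, t, p, p_adjusted, fdr_significant, cohens_d,
#'   effect_r), `significant_ranges` (string), `p_threshold`, plus metadata.
#' @export
compare_metric_curves <- function(curves, metric, contrast, q = 0.05) {
  groups <- contrast_groups(contrast)
  paired <- contrast == "R1_vs_R2"
  dat <- curves[curves$metric == metric & curves$group %in% groups, ]
  if (nrow(dat) == 0) stop("no rows for metric ", metric)
  grid <- sort(unique(dat$sparsity))
  rows <- list()
  for (j in seq_along(grid)) {
    d1 <- dat[dat$sparsity == grid[j] & dat$group == groups[1], ]
    d2 <- dat[dat$sparsity == grid[j] & dat$group == groups[2], ]
    if (nrow(d1) < 2 || nrow(d2) < 2) stop("group size < 2 at sparsity ",
                                           grid[j])
    if (paired) {
      common <- intersect(d1$subject_id, d2$subject_id)
      x <- d1$value[match(common, d1$subject_id)]
      y <- d2$value[match(common, d2$subject_id)]
      ht <- if (sd(x - y) == 0) list(t = 0, p = 1) else paired_ttest(x, y)
    } else {
      x <- d1$value
      y <- d2$value
      ht <- two_sample_ttest_equal_var(x, y)
    }
    d_es <- if (sd(x) > 0 && sd(y) > 0) {
      cohens_d_pooled(mean(x), sd(x), mean(y), sd(y))
    } else NA_real_
    rows[[j]] <- data.frame(
      contrast = contrast, metric = metric, sparsity = grid[j],
      mean_1 = mean(x), sd_1 = sd(x), mean_2 = mean(y), sd_2 = sd(y),
      t_stat = ht$t, p_value = ht$p, cohens_d = d_es,
      effect_r = if (is.na(d_es)) NA_real_ else effect_size_r(d_es),
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  fdr <- fdr_bh(tab$p_value, q)
  tab$p_adjusted <- fdr$p_adjusted
  tab$fdr_significant <- fdr$mask
  names(tab)[names(tab) == "mean_1"] <- paste0("mean_", groups[1])
  names(tab)[names(tab) == "sd_1"] <- paste0("sd_", groups[1])
  names(tab)[names(tab) == "mean_2"] <- paste0("mean_", groups[2])
  names(tab)[names(tab) == "sd_2"] <- paste0("sd_", groups[2])
  structure(list(table = tab,
                 significant_ranges = format_sparsity_ranges(
                   tab$sparsity[tab$fdr_significant], grid),
                 p_threshold = fdr$p_threshold, contrast = contrast,
                 metric = metric, paired = paired, q = q),
            class = "mm_group_comparison")
}

#' Node-level group comparison of per-node normalized clustering
#'
#' Per node: group mean and SD, a paired (R1 vs R2) or pooled (HC contrasts)
#' t-test, BH-FDR across the nodes, Cohen's d of the group summaries and
#' effect-size r. Output follows the conventional regional effect-size table
#' layout (region, coordinates, group gamma summaries, d, effect size, p),
#' sorted by p.
#'
#' @param node_gamma_by_group named list of subjects-x-nodes matrices, one
#'   per group (row names are subject ids; column names node labels). For
#'   the paired contrast both matrices must cover the same subjects.
#' @param contrast `"HC_vs_R1"`, `"HC_vs_R2"` or `"R1_vs_R2"`.
#' @param q FDR level across nodes (default 0.05).
#' @param node_table optional data.frame with `label`, `x_mm`, `y_mm`,
#'   `z_mm` merged into the output.
#' @return an `mm_group_comparison` whose `table` has one row per node.
#' @export
node_level_comparison <- function(node_gamma_by_group, contrast, q = 0.05,
                                  node_table = NULL) {
  groups <- contrast_groups(contrast)
  paired <- contrast == "R1_vs_R2"
  m1 <- node_gamma_by_group[[groups[1]]]
  m2 <- node_gamma_by_group[[groups[2]]]
  if (is.null(m1) || is.null(m2)) stop("missing group matrices for ",
                                       contrast)
  if (!identical(colnames(m1), colnames(m2))) {
    stop("node labels differ between groups")
  }
  if (paired) {
    common <- intersect(rownames(m1), rownames(m2))
    if (length(common) < 2) stop("paired contrast needs >= 2 common subjects")
    m1 <- m1[common, , drop = FALSE]
    m2 <- m2[common, , drop = FALSE]
  }
  nodes <- colnames(m1)
  rows <- lapply(seq_along(nodes), function(i) {
    x <- m1[, i]
    y <- m2[, i]
    ok <- is.finite(x) & is.finite(y)
    if (paired) { x <- x[ok]; y <- y[ok] } else {
      x <- x[is.finite(m1[, i])]; y <- y[is.finite(m2[, i])]
    }
    if (length(x) < 2 || length(y) < 2) {
      return(data.frame(region = nodes[i], mean_1 = NA, sd_1 = NA,
                        mean_2 = NA, sd_2 = NA, t_stat = NA,
                        p_value = NA, cohens_d = NA, effect_r = NA,
                        stringsAsFactors = FALSE))
    }
    ht <- if (paired) {
      if (sd(x - y) == 0) list(t = 0, p = 1) else paired_ttest(x, y)
    } else {
      two_sample_ttest_equal_var(x, y)
    }
    d_es <- cohens_d_pooled(mean(x), sd(x), mean(y), sd(y))
    data.frame(region = nodes[i], mean_1 = mean(x), sd_1 = sd(x),
               mean_2 = mean(y), sd_2 = sd(y), t_stat = ht$t,
               p_value = ht$p, cohens_d = d_es,
               effect_r = effect_size_r(d_es), stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  fdr <- fdr_bh(tab$p_value, q)
  tab$p_adjusted <- fdr$p_adjusted
  tab$fdr_significant <- fdr$mask
  names(tab)[names(tab) == "mean_1"] <- paste0("mean_", groups[1])
  names(tab)[names(tab) == "sd_1"] <- paste0("sd_", groups[1])
  names(tab)[names(tab) == "mean_2"] <- paste0("mean_", groups[2])
  names(tab)[names(tab) == "sd_2"] <- paste0("sd_", groups[2])
  if (!is.null(node_table)) {
    tab <- merge(node_table[, c("label", "x_mm", "y_mm", "z_mm")], tab,
                 by.x = "label", by.y = "region")
    names(tab)[names(tab) == "label"] <- "region"
  }
  tab <- tab[order(tab$p_value), ]
  rownames(tab) <- NULL
  structure(list(table = tab, p_threshold = fdr$p_threshold,
                 contrast = contrast, paired = paired, q = q,
                 significant_nodes = tab$region[tab$fdr_significant %in% TRUE]),
            class = "mm_group_comparison")
}

#' @export
print.mm_group_comparison <- function(x, ...) {
  cat(sprintf("<mm_group_comparison> %s%s, %d units, %d FDR-significant",
              x$contrast, if (x$paired) " (paired)" else "",
              nrow(x$table), sum(x$table$fdr_significant, na.rm = TRUE)))
  if (!is.null(x$significant_ranges) && nzchar(x$significant_ranges)) {
    cat(" [", x$significant_ranges, "]", sep = "")
  }
  cat("\n")
  invisible(x)
}
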