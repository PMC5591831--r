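# Across-subject correlation of per-node clustering between EEG electrodes
# and fMRI ROIs, and export of BrainNet Viewer display files.

#' Cross-modal correlation of node clustering across subjects
#'
#' For every (electrode, ROI) pair, the Pearson correlation across subjects
#' of the per-subject node values (typically R2 - R1 change scores of node
#' gamma). Two-sided p-values come from the t transform with `df = n - 2`;
#' a pair is significant when `|r| > r_min` and `p <= alpha`.
#'
#' @param eeg_node_values subjects x electrodes numeric matrix.
#' @param fmri_node_values subjects x ROIs numeric matrix, same subjects in
#'   the same row order (row names are checked when present).
#' @param r_min correlation magnitude cut (default 0.4).
#' @param alpha p-value cut (default 0.05).
#' @return an object of class `mm_crossmodal`: `r_matrix`, `p_matrix`
#'   (electrodes x ROIs), `significant_pairs` (data.frame electrode, roi, r,
#'   p, n), `n_subjects`, `r_min`, `alpha`.
#' @export
crossmodal_correlation <- function(eeg_node_values, fmri_node_values,
                                   r_min = 0.4, alpha = 0.05) {
  eeg_node_values <- as.matrix(eeg_node_values)
  fmri_node_values <- as.matrix(fmri_node_values)
  if (nrow(eeg_node_values) != nrow(fmri_node_values)) {
    stop("modalities cover different numbers of subjects")
  }
  if (!is.null(rownames(eeg_node_values)) &&
      !is.null(rownames(fmri_node_values)) &&
      !identical(rownames(eeg_node_values), rownames(fmri_node_values))) {
    stop("subject order differs between modalities")
  }
  n <- nrow(eeg_node_values)
  if (n < 4) stop("need at least 4 subjects")
  r <- cor(eeg_node_values, fmri_node_values, use = "pairwise.complete.obs")
  # per-pair n for pairwise-complete data
  ok_e <- !is.na(eeg_node_values)
  ok_f <- !is.na(fmri_node_values)
  n_pair <- crossprod(ok_e, ok_f)
  tstat <- r * sqrt(pmax(n_pair - 2, 0) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(abs(tstat), df = pmax(n_pair - 2, 1), lower.tail = FALSE)
  p[n_pair < 3] <- NA_real_
  sig <- which(!is.na(r) & !is.na(p) & abs(r) > r_min & p <= alpha,
               arr.ind = TRUE)
  pairs <- data.frame(
    electrode = colnames(eeg_node_values)[sig[, 1]] %||%
      as.character(sig[, 1]),
    roi = colnames(fmri_node_values)[sig[, 2]] %||% as.character(sig[, 2]),
    r = r[sig], p = p[sig], n = as.integer(n_pair[sig]),
    stringsAsFactors = FALSE)
  pairs <- pairs[order(pairs$p, -abs(pairs$r)), ]
  rownames(pairs) <- NULL
  structure(list(r_matrix = r, p_matrix = p, n_matrix = n_pair,
                 significant_pairs = pairs, n_subjects = n,
                 r_min = r_min, alpha = alpha),
            class = "mm_crossmodal")
}

#' Restrict cross-modal inputs to significant nodes
#'
#' Keeps only the listed electrodes / ROIs (e.g., those with FDR-significant
#' group effects) before running [crossmodal_correlation()].
#'
#' @param eeg_node_values,fmri_node_values subjects x nodes matrices.
#' @param eeg_sig_nodes,fmri_sig_nodes non-empty character vectors of node
#'   labels present in the respective matrices.
#' @return list with the filtered `eeg` and `fmri` matrices.
#' @export
restrict_to_significant_nodes <- function(eeg_node_values, fmri_node_values,
                                          eeg_sig_nodes, fmri_sig_nodes) {
  eeg_node_values <- as.matrix(eeg_node_values)
  fmri_node_values <- as.matrix(fmri_node_values)
  if (length(eeg_sig_nodes) == 0 || length(fmri_sig_nodes) == 0) {
    stop("significant node lists must be non-empty")
  }
  missing_e <- setdiff(eeg_sig_nodes, colnames(eeg_node_values))
  missing_f <- setdiff(fmri_sig_nodes, colnames(fmri_node_values))
  if (length(missing_e) > 0) stop("unknown EEG node label(s): ",
                                  paste(missing_e, collapse = ", "))
  if (length(missing_f) > 0) stop("unknown fMRI node label(s): ",
                                  paste(missing_f, collapse = ", "))
  list(eeg = eeg_node_values[, eeg_sig_nodes, drop = FALSE],
       fmri = fmri_node_values[, fmri_sig_nodes, drop = FALSE])
}

#' Export nodes in the BrainNet Viewer .node format
#'
#' One line per node: `x y z color size label` (space-separated). Sizes are
#' typically effect sizes so rendered spheres scale with the effect; the
#' color column is an integer modality code.
#'
#' @param node_table data.frame with `label`, `x_mm`, `y_mm`, `z_mm`.
#' @param values numeric vector aligned to `node_table` rows (sphere sizes).
#' @param out_path output file path.
#' @param color integer color code (single value or per-node vector).
#' @return `out_path`, invisibly.
#' @export
export_brainnet_nodes <- function(node_table, values, out_path, color = 1L) {
  if (nrow(node_table) == 0) {
    writeLines(character(0), out_path)
    return(invisible(out_path))
  }
  if (length(values) != nrow(node_table)) {
    stop("values length must match node table rows")
  }
  if (any(!is.finite(values))) stop("non-finite node value(s)")
  color <- rep_len(as.integer(color), nrow(node_table))
  lines <- sprintf("%g %g %g %d %g %s", node_table$x_mm, node_table$y_mm,
                   node_table$z_mm, color, values, node_table$label)
  writeLines(lines, out_path)
  invisible(out_path)
}

#' @rdname export_brainnet_nodes
#' @param path a .node file written by [export_brainnet_nodes()].
#' @return for `read_brainnet_nodes`: data.frame with x_mm, y_mm, z_mm,
#'   color, size, label.
#' @export
read_brainnet_nodes <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0) {
    return(data.frame(x_mm = numeric(0), y_mm = numeric(0),
                      z_mm = numeric(0), color = integer(0),
                      size = numeric(0), label = character(0)))
  }
  parts <- strsplit(lines, " +")
  data.frame(
    x_mm = vapply(parts, function(p) as.numeric(p[1]), numeric(1)),
    y_mm = vapply(parts, function(p) as.numeric(p[2]), numeric(1)),
    z_mm = vapply(parts, function(p) as.numeric(p[3]), numeric(1)),
    color = vapply(parts, function(p) as.integer(p[4]), integer(1)),
    size = vapply(parts, function(p) as.numeric(p[5]), numeric(1)),
    label = vapply(parts, function(p) p[6], character(1)),
    stringsAsFactors = FALSE)
}

#' Bundled reference table of regions with significant post-rTMS effects
#'
#' Regional normalized-clustering summaries (mean +/- SD for the R1 and R2
#' sessions), Cohen's d, effect-size r and p-values for the electrodes and
#' ROIs reported as significantly altered by a single 1 Hz rTMS session in
#' the motivating simultaneous EEG-fMRI study of writer's cramp, with their
#' MNI coordinates. Used as a desk-check input for the effect-size
#' calculators and as a template for exports.
#'
#' @return data.frame with columns modality, region, x_mm, y_mm, z_mm,
#'   r1_gamma_mean, r1_gamma_sd, r2_gamma_mean, r2_gamma_sd, cohens_d,
#'   effect_size, p_value.
#' @export
reference_region_table <- function() {
  path <- system.file("extdata", "reference_regions.tsv", package = "mmgraph")
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
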