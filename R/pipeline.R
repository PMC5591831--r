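# End-to-end orchestration: synthetic or on-disk cohort -> preprocessing ->
# connectivity -> small-world curves -> group statistics -> cross-modal
# correlation, with every output carrying the config hash and seed.

#' Study configuration
#'
#' Validates and freezes every tunable of a full pipeline run. Exactly one
#' data source is used: an in-memory cohort, a cohort directory (as written
#' by [write_cohort()]), or a synthetic cohort spec (the default when all are
#' `NULL`, built from `seed`).
#'
#' @param cohort optional `mm_cohort`.
#' @param cohort_dir optional directory readable by [read_cohort()].
#' @param synthetic_spec optional `mm_cohort_spec`.
#' @param band EEG band used for inferential outputs (default `"beta2"`).
#' @param bands named band list (default [default_eeg_bands()]).
#' @param grid sparsity grid (default [sparsity_grid()]).
#' @param n_null null-ensemble size per graph.
#' @param swaps_per_edge rewiring effort per reference.
#' @param epoch_length_s,reject_uv EEG epoching and rejection settings.
#' @param eeg_band_limits broad EEG band-pass applied before band splitting.
#' @param fmri_band fMRI temporal band-pass (Hz).
#' @param n_initial_dynamics leading dynamics dropped from on-disk
#'   recordings (synthetic cohorts are generated post-drop and skip this).
#' @param tr_s repetition time in seconds, used to convert dropped dynamics
#'   to EEG samples.
#' @param q FDR level for group statistics.
#' @param r_min,alpha cross-modal significance rule.
#' @param use_change_scores correlate R2 - R1 change scores across subjects
#'   (default) rather than R2 values alone.
#' @param band_summary also compute the all-band group summary (on a thinned
#'   grid, every `band_summary_stride`-th level).
#' @param band_summary_stride grid thinning for the band summary.
#' @param strength edge-strength convention for thresholding.
#' @param seed master seed for every stochastic step.
#' @param out_dir optional output directory; when set, all result tables,
#'   .node files and a MANIFEST.json are written.
#' @return a validated list of class `mm_study_config`.
#' @export
study_config <- function(cohort = NULL, cohort_dir = NULL,
                         synthetic_spec = NULL, band = "beta2",
                         bands = default_eeg_bands(),
                         grid = sparsity_grid(), n_null = 100,
                         swaps_per_edge = 10, epoch_length_s = 3,
                         reject_uv = 150, eeg_band_limits = c(0.5, 45),
                         fmri_band = c(0.01, 0.09),
                         n_initial_dynamics = 5, tr_s = 3, q = 0.05, r_min = 0.4,
                         alpha = 0.05, use_change_scores = TRUE,
                         band_summary = TRUE, band_summary_stride = 5,
                         strength = "absolute", seed = 1L, out_dir = NULL) {
  if (!is.null(cohort) && !inherits(cohort, "mm_cohort")) {
    stop("cohort must be an mm_cohort")
  }
  if (is.null(cohort) && is.null(cohort_dir) && is.null(synthetic_spec)) {
    synthetic_spec <- synthetic_cohort_spec(seed = seed)
  }
  if (!is.null(synthetic_spec) &&
      !inherits(synthetic_spec, "mm_cohort_spec")) {
    stop("synthetic_spec must be an mm_cohort_spec")
  }
  if (!band %in% names(bands)) stop("band '", band, "' not in bands")
  if (any(diff(grid) <= 0)) stop("grid must be strictly increasing")
  if (n_null < 1) stop("n_null must be >= 1")
  if (!(q > 0 && q < 1)) stop("q must lie in (0, 1)")
  if (r_min < 0 || r_min >= 1) stop("r_min must lie in [0, 1)")
  structure(list(cohort = cohort, cohort_dir = cohort_dir,
                 synthetic_spec = synthetic_spec, band = band, bands = bands,
                 grid = grid, n_null = n_null,
                 swaps_per_edge = swaps_per_edge,
                 epoch_length_s = epoch_length_s, reject_uv = reject_uv,
                 eeg_band_limits = eeg_band_limits, fmri_band = fmri_band,
                 n_initial_dynamics = n_initial_dynamics, tr_s = tr_s, q = q,
                 r_min = r_min, alpha = alpha,
                 use_change_scores = use_change_scores,
                 band_summary = band_summary,
                 band_summary_stride = band_summary_stride,
                 strength = strength, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "mm_study_config")
}

config_digest <- function(config) {
  hashable <- config[!(names(config) %in% c("cohort", "out_dir"))]
  if (!is.null(hashable$synthetic_spec)) {
    hashable$synthetic_spec <- unclass(hashable$synthetic_spec)
  }
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(hashable, tmp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  unname(tools::md5sum(tmp))
}

#' Validate a cohort against the pipeline's expectations
#'
#' Reporting-only checks: node counts against node tables, positive sampling
#' metadata, R1/R2 pairing completeness, constant channels. Never raises.
#'
#' @param cohort an `mm_cohort`.
#' @return data.frame with columns `check`, `recording_id`, `detail`
#'   (zero rows when the cohort is clean).
#' @export
validate_inputs <- function(cohort) {
  stopifnot(inherits(cohort, "mm_cohort"))
  bad <- list()
  note <- function(check, rid, detail) {
    bad[[length(bad) + 1L]] <<- data.frame(check = check,
                                           recording_id = rid,
                                           detail = detail,
                                           stringsAsFactors = FALSE)
  }
  man <- cohort$manifest
  for (i in seq_len(nrow(man))) {
    rid <- man$recording_id[i]
    ts <- cohort$recordings[[rid]]
    if (is.null(ts)) { note("missing_recording", rid, "not in cohort"); next }
    nt <- cohort$node_tables[[man$modality[i]]]
    if (!is.null(nt) && nrow(ts$values) != nrow(nt)) {
      note("node_count_mismatch", rid,
           sprintf("%d channels vs %d node-table rows", nrow(ts$values),
                   nrow(nt)))
    }
    if (!is.finite(ts$sampling_rate) || ts$sampling_rate <= 0) {
      note("bad_sampling_rate", rid, as.character(ts$sampling_rate))
    }
    sds <- apply(ts$values, 1, sd)
    if (any(sds == 0)) {
      note("constant_channel", rid,
           paste(ts$node_labels[sds == 0], collapse = ","))
    }
  }
  paired <- man[man$group %in% c("R1", "R2"), ]
  for (mod in unique(paired$modality)) {
    pm <- paired[paired$modality == mod, ]
    r1 <- pm$subject_id[pm$group == "R1"]
    r2 <- pm$subject_id[pm$group == "R2"]
    for (s in setdiff(r2, r1)) {
      note("pairing_violation", sprintf("%s_R2_%s", s, mod),
           "R2 recording lacks its R1 pair")
    }
    for (s in setdiff(r1, r2)) {
      note("pairing_violation", sprintf("%s_R1_%s", s, mod),
           "R1 recording lacks its R2 pair")
    }
  }
  if (length(bad) == 0) {
    return(data.frame(check = character(0), recording_id = character(0),
                      detail = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, bad)
}

# Deterministic per-recording seed block: each recording's sparsity sweep
# consumes length(grid) * (n_null + 1) seeds.
recording_seed <- function(base_seed, index, grid_len, n_null) {
  block <- as.numeric(grid_len) * (n_null + 1) + 1
  (as.numeric(base_seed) + (index - 1) * block) %% 2147483647
}

preprocess_eeg_recording <- function(ts, config) {
  nyq <- ts$sampling_rate / 2
  hi <- min(config$eeg_band_limits[2], nyq * 0.98)
  ts <- bandpass_filter(ts, config$eeg_band_limits[1], hi)
  er <- epoch_and_reject(ts, config$epoch_length_s, config$reject_uv)
  list(ts = er$ts, report = er$report)
}

preprocess_fmri_recording <- function(ts, config, confounds = NULL) {
  ts <- regress_nuisance(ts, confounds)
  nyq <- ts$sampling_rate / 2
  if (config$fmri_band[2] < nyq) {
    ts <- bandpass_filter(ts, config$fmri_band[1], config$fmri_band[2])
  }
  ts
}

curve_for_recording <- function(ts, config, index, band = NA_character_) {
  cm <- correlation_matrix(ts)
  attr(cm, "band") <- band
  metrics_over_sparsity(cm, grid = config$grid, n_null = config$n_null,
                        seed = recording_seed(config$seed, index,
                                              length(config$grid),
                                              config$n_null),
                        swaps_per_edge = config$swaps_per_edge,
                        strength = config$strength)
}

node_gamma_matrices <- function(curves, manifest_rows) {
  split_by <- split(seq_along(curves), manifest_rows$group)
  out <- list()
  for (g in names(split_by)) {
    idx <- split_by[[g]]
    mat <- do.call(rbind, lapply(idx, function(i) node_gamma_summary(curves[[i]])))
    rownames(mat) <- manifest_rows$subject_id[idx]
    out[[g]] <- mat
  }
  out
}

change_score_matrix <- function(node_gamma_by_group, use_change_scores) {
  m1 <- node_gamma_by_group$R1
  m2 <- node_gamma_by_group$R2
  common <- intersect(rownames(m1), rownames(m2))
  if (use_change_scores) {
    m2[common, , drop = FALSE] - m1[common, , drop = FALSE]
  } else {
    m2[common, , drop = FALSE]
  }
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full multi-modal study pipeline
#'
#' Executes preprocessing, connectivity, small-world curves, group statistics
#' and cross-modal correlation for both modalities of a cohort, mirroring
#' the multi-modal EEG-fMRI graph workflow: per-sparsity group curves, an
#' all-band summary, regional effect-size tables, a cross-modal pair table
#' and BrainNet .node display files. When `config$out_dir` is set, all
#' artifacts plus a MANIFEST.json (config hash, seed, per-stage logs,
#' checksums) are written; a failing stage aborts with the stage named and
#' the MANIFEST records the incompleteness.
#'
#' @param config an `mm_study_config`.
#' @return an object of class `mm_study_result`: `curves` (long data.frame),
#'   `band_summary`, `curve_comparisons` (per modality x metric x contrast),
#'   `node_comparisons` (per modality), `crossmodal`, `validation`,
#'   `epoch_reports`, `config_hash`, `seed`, `output_files`.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "mm_study_config"))
  hash <- config_digest(config)
  out_dir <- config$out_dir
  manifest_log <- list(config_hash = hash, seed = config$seed,
                       complete = FALSE, stages = list())
  finalize_manifest <- function() {
    if (!is.null(out_dir)) {
      jsonlite::write_json(manifest_log, file.path(out_dir, "MANIFEST.json"),
                           auto_unbox = TRUE, digits = NA, null = "null",
                           pretty = TRUE)
    }
  }
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)
  on.exit(finalize_manifest())

  cohort <- run_stage("load_cohort", {
    if (!is.null(config$cohort)) config$cohort
    else if (!is.null(config$cohort_dir)) read_cohort(config$cohort_dir)
    else generate_cohort(config$synthetic_spec)
  })
  synthetic <- is.null(config$cohort_dir) && is.null(config$cohort)
  validation <- run_stage("validate_inputs", validate_inputs(cohort))
  manifest_log$stages$validate_inputs <- list(n_violations = nrow(validation))

  man <- cohort$manifest
  epoch_reports <- list()
  curves <- list()          # recording_id -> inferential-band curve
  band_curves <- list()     # band summary curves (thinned grid)
  summary_grid <- config$grid[seq(1, length(config$grid),
                                  by = config$band_summary_stride)]

  eeg_rows <- which(man$modality == "eeg")
  fmri_rows <- which(man$modality == "fmri")

  run_stage("preprocess_eeg", {
    for (i in eeg_rows) {
      rid <- man$recording_id[i]
      ts <- cohort$recordings[[rid]]
      if (!synthetic && config$n_initial_dynamics > 0) {
        ts <- drop_initial_dynamics(ts, config$n_initial_dynamics,
                                    tr_s = config$tr_s)
      }
      pre <- preprocess_eeg_recording(ts, config)
      epoch_reports[[rid]] <- pre$report
      cohort$recordings[[rid]] <- pre$ts
    }
  })
  manifest_log$stages$preprocess_eeg <- list(
    n_recordings = length(eeg_rows),
    epochs_kept = vapply(epoch_reports, function(r) r$n_kept, numeric(1)))

  run_stage("preprocess_fmri", {
    for (i in fmri_rows) {
      rid <- man$recording_id[i]
      ts <- cohort$recordings[[rid]]
      if (!synthetic && config$n_initial_dynamics > 0) {
        ts <- drop_initial_dynamics(ts, config$n_initial_dynamics)
      }
      cohort$recordings[[rid]] <- preprocess_fmri_recording(ts, config)
    }
  })
  manifest_log$stages$preprocess_fmri <- list(n_recordings = length(fmri_rows))

  run_stage("graph_metrics", {
    for (i in seq_len(nrow(man))) {
      rid <- man$recording_id[i]
      ts <- cohort$recordings[[rid]]
      if (man$modality[i] == "eeg") {
        bands_ts <- split_bands(ts, config$bands)
        curves[[rid]] <- curve_for_recording(bands_ts[[config$band]], config,
                                              i, band = config$band)
        if (config$band_summary) {
          for (b in names(bands_ts)) {
            if (b == config$band) next
            key <- paste(rid, b, sep = ".")
            cm <- correlation_matrix(bands_ts[[b]])
            attr(cm, "band") <- b
            band_curves[[key]] <- metrics_over_sparsity(
              cm, grid = summary_grid, n_null = config$n_null,
              seed = recording_seed(config$seed, nrow(man) + i,
                                    length(config$grid), config$n_null),
              swaps_per_edge = config$swaps_per_edge,
              strength = config$strength)
          }
        }
      } else {
        curves[[rid]] <- curve_for_recording(ts, config, i)
      }
    }
  })
  manifest_log$stages$graph_metrics <- list(
    n_curves = length(curves), n_null = config$n_null,
    grid = config$grid,
    edges_per_level = if (length(curves) > 0)
      curves[[1]]$table$n_edges else NULL)

  curves_long <- do.call(rbind, lapply(curves, curve_long))
  if (config$band_summary) {
    bs_long <- rbind(
      do.call(rbind, lapply(band_curves, curve_long)),
      do.call(rbind, lapply(curves[man$recording_id[eeg_rows]], function(cv) {
        cl <- curve_long(cv)
        cl[cl$sparsity %in% summary_grid, ]
      })))
    band_summary <- stats::aggregate(value ~ band + group + metric,
                                     data = bs_long, FUN = mean)
  } else {
    band_summary <- NULL
  }

  comparisons <- run_stage("group_statistics", {
    out <- list()
    for (mod in c("eeg", "fmri")) {
      rows <- man$modality == mod
      cl <- curves_long[curves_long$modality == mod, ]
      for (metric in c("gamma", "lambda", "sigma")) {
        for (ct in c("HC_vs_R1", "HC_vs_R2", "R1_vs_R2")) {
          if (!all(contrast_groups(ct) %in% unique(cl$group))) next
          out[[paste(mod, metric, ct, sep = ".")]] <-
            compare_metric_curves(cl, metric, ct, q = config$q)
        }
      }
    }
    out
  })

  node_comparisons <- run_stage("node_statistics", {
    out <- list()
    for (mod in c("eeg", "fmri")) {
      idx <- which(man$modality == mod)
      ng <- node_gamma_matrices(curves[man$recording_id[idx]], man[idx, ])
      if (all(c("R1", "R2") %in% names(ng))) {
        out[[mod]] <- node_level_comparison(ng, "R1_vs_R2", q = config$q,
                                            node_table = cohort$node_tables[[mod]])
        attr(out[[mod]], "node_gamma") <- ng
      }
    }
    out
  })

  crossmodal <- run_stage("crossmodal", {
    sig_e <- node_comparisons$eeg$significant_nodes
    sig_f <- node_comparisons$fmri$significant_nodes
    if (length(node_comparisons) < 2 || length(sig_e) == 0 ||
        length(sig_f) == 0) {
      NULL
    } else {
      ch_e <- change_score_matrix(attr(node_comparisons$eeg, "node_gamma"),
                                  config$use_change_scores)
      ch_f <- change_score_matrix(attr(node_comparisons$fmri, "node_gamma"),
                                  config$use_change_scores)
      common <- intersect(rownames(ch_e), rownames(ch_f))
      if (length(common) < 4) {
        NULL   # too few paired subjects for an across-subject correlation
      } else {
        filt <- restrict_to_significant_nodes(ch_e[common, , drop = FALSE],
                                              ch_f[common, , drop = FALSE],
                                              sig_e, sig_f)
        crossmodal_correlation(filt$eeg, filt$fmri, r_min = config$r_min,
                               alpha = config$alpha)
      }
    }
  })

  result <- structure(
    list(curves = curves_long, band_summary = band_summary,
         curve_comparisons = comparisons, node_comparisons = node_comparisons,
         crossmodal = crossmodal, validation = validation,
         epoch_reports = epoch_reports, config_hash = hash,
         seed = config$seed, output_files = character(0)),
    class = "mm_study_result")

  if (!is.null(out_dir)) {
    result$output_files <- run_stage("write_outputs", {
      write_study_outputs(result, cohort, config, out_dir)
    })
    manifest_log$files <- as.list(
      setNames(unname(tools::md5sum(result$output_files)),
               basename(result$output_files)))
  }
  manifest_log$complete <- TRUE
  result
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

write_study_outputs <- function(result, cohort, config, out_dir) {
  files <- character(0)
  files <- c(files, write_tsv(result$curves,
                              file.path(out_dir, "curves.tsv")))
  if (!is.null(result$band_summary)) {
    files <- c(files, write_tsv(result$band_summary,
                                file.path(out_dir, "band_summary.tsv")))
  }
  cmp_tab <- do.call(rbind, lapply(names(result$curve_comparisons), function(k) {
    tab <- result$curve_comparisons[[k]]$table
    tab$modality <- strsplit(k, ".", fixed = TRUE)[[1]][1]
    names(tab)[grep("^mean_|^sd_", names(tab))] <-
      c("mean_g1", "sd_g1", "mean_g2", "sd_g2")
    tab
  }))
  files <- c(files, write_tsv(cmp_tab,
                              file.path(out_dir, "curve_comparisons.tsv")))
  sig_ranges <- lapply(result$curve_comparisons, function(x)
    x$significant_ranges)
  jsonlite::write_json(sig_ranges,
                       file.path(out_dir, "significant_ranges.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- c(files, file.path(out_dir, "significant_ranges.json"))
  for (mod in names(result$node_comparisons)) {
    nc <- result$node_comparisons[[mod]]
    files <- c(files, write_tsv(nc$table,
                                file.path(out_dir,
                                          sprintf("node_table_%s.tsv", mod))))
    sig <- nc$table[nc$table$fdr_significant %in% TRUE, , drop = FALSE]
    node_path <- file.path(out_dir, sprintf("%s.node", mod))
    if (nrow(sig) > 0 && all(c("x_mm", "y_mm", "z_mm") %in% names(sig))) {
      export_brainnet_nodes(sig[, c("region", "x_mm", "y_mm", "z_mm")] |>
                              (\(d) { names(d)[1] <- "label"; d })(),
                            values = abs(effect_size_r(sig$cohens_d)),
                            out_path = node_path,
                            color = if (mod == "eeg") 1L else 2L)
    } else {
      writeLines(character(0), node_path)
    }
    files <- c(files, node_path)
  }
  cm_path <- file.path(out_dir, "crossmodal.tsv")
  if (!is.null(result$crossmodal)) {
    files <- c(files, write_tsv(result$crossmodal$significant_pairs, cm_path))
  } else {
    files <- c(files, write_tsv(
      data.frame(electrode = character(0), roi = character(0),
                 r = numeric(0), p = numeric(0), n = integer(0)), cm_path))
  }
  files
}

#' @export
print.mm_study_result <- function(x, ...) {
  cat("<mm_study_result>\n")
  cat(sprintf("  curves: %d rows; comparisons: %d; config %s, seed %d\n",
              nrow(x$curves), length(x$curve_comparisons), x$config_hash,
              x$seed))
  for (mod in names(x$node_comparisons)) {
    sig <- x$node_comparisons[[mod]]$significant_nodes
    cat(sprintf("  %s significant nodes: %s\n", mod,
                if (length(sig)) paste(sig, collapse = ", ") else "(none)"))
  }
  if (!is.null(x$crossmodal)) {
    cat(sprintf("  crossmodal significant pairs: %d\n",
                nrow(x$crossmodal$significant_pairs)))
  }
  invisible(x)
}
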