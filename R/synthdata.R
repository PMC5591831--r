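# Synthetic ground-truth graphs, subject time series and full cohorts with
# planted small-world effects, so every pipeline stage is testable without
# patient recordings.

#' Generate a Watts-Strogatz small-world graph
#'
#' Ring lattice on `n_nodes` nodes where each node connects to its `k`
#' nearest neighbours, followed by uniform rewiring of the far endpoint of
#' each lattice edge with probability `p_rewire`. Rewiring never creates
#' self-loops or duplicate edges and always preserves the total edge count
#' `n_nodes * k / 2`.
#'
#' @param n_nodes number of nodes (must exceed `k`).
#' @param k even lattice degree (each node's number of ring neighbours).
#' @param p_rewire rewiring probability in `[0, 1]`; `0` returns the pure
#'   lattice, `1` an edge-count-matched random graph.
#' @param seed integer seed; generation is reproducible for a fixed seed.
#' @return an object of class `mm_ground_truth_graph` with fields
#'   `adjacency` (0/1 symmetric integer matrix, zero diagonal), `n_nodes`,
#'   `ring_degree`, `rewire_prob` and `seed`.
#' @export
generate_small_world_graph <- function(n_nodes, k, p_rewire, seed) {
  if (k %% 2 != 0) stop("k must be even")
  if (k < 2) stop("k must be at least 2")
  if (k >= n_nodes) stop("k must be smaller than n_nodes")
  if (p_rewire < 0 || p_rewire > 1) stop("p_rewire must lie in [0, 1]")
  set.seed(as.integer(seed))
  adj <- matrix(0L, n_nodes, n_nodes)
  for (i in seq_len(n_nodes)) {
    for (off in seq_len(k / 2)) {
      j <- ((i - 1 + off) %% n_nodes) + 1
      adj[i, j] <- adj[j, i] <- 1L
    }
  }
  if (p_rewire > 0) {
    for (i in seq_len(n_nodes)) {
      for (off in seq_len(k / 2)) {
        j <- ((i - 1 + off) %% n_nodes) + 1
        if (runif(1) < p_rewire) {
          candidates <- which(adj[i, ] == 0L)
          candidates <- setdiff(candidates, i)
          if (length(candidates) == 0L) next  # node saturated, keep edge
          jnew <- candidates[sample.int(length(candidates), 1L)]
          adj[i, j] <- adj[j, i] <- 0L
          adj[i, jnew] <- adj[jnew, i] <- 1L
        }
      }
    }
  }
  structure(
    list(adjacency = adj, n_nodes = n_nodes, ring_degree = k,
         rewire_prob = p_rewire, seed = as.integer(seed)),
    class = "mm_ground_truth_graph")
}

# Disjoint contiguous blocks of nodes: the "local clusters" used for
# planting within-cluster coupling effects. A complete-graph mask over
# disjoint blocks has smallest eigenvalue -1 regardless of block size, so an
# additive coupling boost below the base covariance's positive-definiteness
# margin is always safe.
cluster_mask <- function(n, cluster_size = 8) {
  block <- (seq_len(n) - 1) %/% cluster_size
  mask <- outer(block, block, "==")
  diag(mask) <- FALSE
  mask
}

#' Build a positive-definite covariance from a planted graph
#'
#' Returns `Sigma = I + coupling * A (+ boost * W)` where `A` is the graph
#' adjacency and `W` an optional extra-coupling mask (e.g., disjoint node
#' clusters from the cohort generator). Adjacent node pairs get strictly
#' larger covariance than non-adjacent, non-boosted pairs, so Pearson
#' correlation of time series drawn from `Sigma` recovers the planted
#' topology. `coupling` below `1 / lambda_max(A)` is always safe for the base
#' term (the adjacency is non-negative, so its spectral radius bounds the
#' most negative eigenvalue); a boost on a disjoint-clique mask subtracts at
#' most `boost` from the smallest eigenvalue. Positive definiteness is
#' verified by eigendecomposition and violation is a hard error.
#'
#' @param graph an `mm_ground_truth_graph` or a 0/1 adjacency matrix.
#' @param coupling_strength covariance added per planted edge.
#' @param boost_mask optional logical matrix of node pairs receiving extra
#'   coupling (symmetric, ignored on the diagonal).
#' @param boost extra covariance added on `boost_mask` pairs.
#' @return symmetric positive-definite covariance matrix.
#' @export
covariance_from_graph <- function(graph, coupling_strength,
                                  boost_mask = NULL, boost = 0) {
  adj <- if (inherits(graph, "mm_ground_truth_graph")) graph$adjacency
         else as.matrix(graph)
  n <- nrow(adj)
  sigma <- diag(n) + coupling_strength * adj
  if (!is.null(boost_mask) && boost != 0) {
    bm <- boost_mask & !diag(TRUE, n)
    sigma[bm] <- sigma[bm] + boost
  }
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10) {
    stop(sprintf(paste0("covariance is not positive definite (smallest ",
                        "eigenvalue %.3g); reduce coupling_strength (< 1/",
                        "lambda_max(A) is always safe) or the boost"),
                 min(ev)))
  }
  sigma
}

#' Draw a stationary multivariate Gaussian recording
#'
#' Samples `n_samples` i.i.d. (or AR(1), if `ar > 0`) multivariate normal
#' vectors with the given covariance and wraps them as an
#' [time_series_matrix()]. With AR(1) innovation scaling
#' `sqrt(1 - ar^2)`, the stationary cross-channel covariance equals
#' `covariance` exactly, so Pearson-correlation analyses are unaffected while
#' temporal filters have autocorrelation to act on.
#'
#' @param covariance positive-definite node covariance.
#' @param n_samples number of time points; at least `10 * n_nodes` is
#'   recommended for stable correlation estimates.
#' @param sampling_rate passed to [time_series_matrix()].
#' @param modality `"eeg"` or `"fmri"`.
#' @param seed integer seed.
#' @param ar AR(1) coefficient in `[0, 1)`; default 0 (white).
#' @inheritParams time_series_matrix
#' @return an `mm_timeseries` (nodes x samples).
#' @export
generate_subject_timeseries <- function(covariance, n_samples, sampling_rate,
                                        modality, seed, ar = 0,
                                        subject_id = NA_character_,
                                        group = NA_character_,
                                        node_labels = NULL) {
  n <- nrow(covariance)
  ev <- eigen(covariance, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10) stop("covariance must be positive definite")
  if (ar < 0 || ar >= 1) stop("ar must lie in [0, 1)")
  set.seed(as.integer(seed))
  cf <- chol(covariance)
  innov <- t(cf) %*% matrix(rnorm(n * n_samples), n, n_samples)
  if (ar > 0) {
    x <- matrix(0, n, n_samples)
    scale <- sqrt(1 - ar^2)
    x[, 1] <- innov[, 1]
    for (t in 2:n_samples) x[, t] <- ar * x[, t - 1] + scale * innov[, t]
    innov <- x
  }
  time_series_matrix(innov, sampling_rate, modality, subject_id = subject_id,
                     group = group, node_labels = node_labels)
}

#' Specification of a synthetic EEG-fMRI cohort
#'
#' Default sizes mirror the motivating study design: 14 patients recorded
#' before (R1) and immediately after (R2) a 1 Hz rTMS session, 20 healthy
#' controls recorded once, 31 EEG scalp electrodes at 250 Hz and 160 fMRI
#' ROIs at TR = 3 s for 180 retained volumes. Each subject gets a
#' Watts-Strogatz base graph per modality; R2 covariances add
#' `clustering_boost` extra coupling on within-cluster pairs (disjoint
#' contiguous blocks of `cluster_size` nodes), which tilts edge ranking at a
#' fixed sparsity toward triangle-closing local pairs and so raises binarized
#' clustering at matched density. HC covariances add `hc_boost` (default half
#' the R2 boost), planting the ordering R1 < HC < R2 in clustering, as
#' expected when disease lowers local clustering and stimulation restores and
#' overshoots it. Per-subject boost magnitudes are jittered uniformly in
#' `[0.75, 1.25] * clustering_boost` and shared across the two modalities so
#' cross-modal change-score correlations are plantable.
#'
#' @param n_paired_subjects patients with paired R1/R2 recordings.
#' @param n_hc_subjects unpaired healthy controls.
#' @param n_eeg_channels,n_fmri_rois node counts per modality.
#' @param eeg_samples EEG samples per recording (default 540 s at 250 Hz).
#' @param eeg_sampling_rate EEG rate in Hz.
#' @param fmri_volumes retained fMRI volumes.
#' @param fmri_tr repetition time in seconds.
#' @param ws_k_eeg,ws_k_fmri even lattice degrees of the base graphs.
#' @param ws_p rewiring probability of the base graphs.
#' @param cluster_size nodes per planted cluster block.
#' @param coupling covariance per planted edge.
#' @param clustering_boost extra within-cluster coupling in R2
#'   (`delta >= 0`); 0 generates a null cohort.
#' @param hc_boost within-cluster coupling in HC; default
#'   `clustering_boost / 2`.
#' @param noise_sd observation noise SD added to each channel.
#' @param seed master seed; per-subject sub-seeds are derived
#'   deterministically from it.
#' @return a validated list of class `mm_cohort_spec`.
#' @export
synthetic_cohort_spec <- function(n_paired_subjects = 14, n_hc_subjects = 20,
                                  n_eeg_channels = 31, n_fmri_rois = 160,
                                  eeg_samples = 135000,
                                  eeg_sampling_rate = 250,
                                  fmri_volumes = 180, fmri_tr = 3,
                                  ws_k_eeg = 6, ws_k_fmri = 16, ws_p = 0.1,
                                  cluster_size = 8, coupling = 0.12,
                                  clustering_boost = 0.2,
                                  hc_boost = clustering_boost / 2,
                                  noise_sd = 0.5, seed = 1L) {
  spec <- list(n_paired_subjects = n_paired_subjects,
               n_hc_subjects = n_hc_subjects,
               n_eeg_channels = n_eeg_channels, n_fmri_rois = n_fmri_rois,
               eeg_samples = eeg_samples,
               eeg_sampling_rate = eeg_sampling_rate,
               fmri_volumes = fmri_volumes, fmri_tr = fmri_tr,
               ws_k_eeg = ws_k_eeg, ws_k_fmri = ws_k_fmri, ws_p = ws_p,
               cluster_size = cluster_size,
               coupling = coupling, clustering_boost = clustering_boost,
               hc_boost = hc_boost, noise_sd = noise_sd,
               seed = as.integer(seed))
  counts <- c("n_paired_subjects", "n_hc_subjects", "n_eeg_channels",
              "n_fmri_rois", "eeg_samples", "fmri_volumes")
  for (f in counts) {
    if (spec[[f]] < 1) stop(f, " must be a positive count")
  }
  if (spec$clustering_boost < 0) stop("clustering_boost must be >= 0")
  if (spec$hc_boost < 0) stop("hc_boost must be >= 0")
  if (spec$noise_sd <= 0) stop("noise_sd must be positive")
  if (ws_k_eeg %% 2 != 0 || ws_k_fmri %% 2 != 0) {
    stop("lattice degrees must be even")
  }
  class(spec) <- "mm_cohort_spec"
  spec
}

# 31 scalp labels of the 10-20/10-10 montage used for synthetic EEG nodes.
eeg_channel_labels_31 <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "FC5", "FC1", "FC2", "FC6",
    "T7", "C3", "Cz", "C4", "T8", "TP9", "CP5", "CP1", "CP2", "CP6", "TP10",
    "P7", "P3", "Pz", "P4", "P8", "POz", "O1", "Oz", "O2")
}

# Deterministic synthetic node coordinates: points on a scalp-/brain-like
# ellipsoid (EEG) or jittered grid in a brain-sized box (fMRI). Purely
# synthetic stand-ins for user-supplied montage / atlas tables.
synthetic_node_table <- function(n, modality) {
  idx <- seq_len(n) - 1
  golden <- pi * (3 - sqrt(5))
  zfrac <- 1 - idx / max(n - 1, 1)          # upper hemisphere for EEG
  theta <- golden * idx
  if (modality == "eeg") {
    labels <- if (n == 31) eeg_channel_labels_31()
              else sprintf("E%02d", seq_len(n))
    r <- sqrt(pmax(0, 1 - zfrac^2))
    data.frame(label = labels,
               x_mm = round(80 * r * cos(theta), 1),
               y_mm = round(95 * r * sin(theta), 1),
               z_mm = round(70 * zfrac, 1),
               network = "scalp", stringsAsFactors = FALSE)
  } else {
    zfrac <- 2 * zfrac - 1
    r <- sqrt(pmax(0, 1 - zfrac^2))
    data.frame(label = sprintf("ROI_%03d", seq_len(n)),
               x_mm = round(65 * r * cos(theta), 1),
               y_mm = round(85 * r * sin(theta), 1),
               z_mm = round(60 * zfrac, 1),
               network = "synthetic", stringsAsFactors = FALSE)
  }
}

#' Generate a full synthetic EEG-fMRI cohort
#'
#' Produces one EEG and one fMRI recording per subject-session (R1 and R2 for
#' each paired patient, one session per healthy control), a manifest
#' recording group membership and R1/R2 pairing, and per-modality node
#' tables. See [synthetic_cohort_spec()] for the planted-effect model.
#'
#' @param spec an `mm_cohort_spec`.
#' @return a list of class `mm_cohort` with elements `recordings` (named list
#'   of `mm_timeseries`), `manifest` (data.frame: subject_id, group,
#'   modality, recording_id, pair_id), `node_tables` (list eeg/fmri) and
#'   `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "mm_cohort_spec"))
  set.seed(spec$seed)
  n_sub <- spec$n_paired_subjects + spec$n_hc_subjects
  # master-seed-derived sub-seeds: graphs, boosts, one per recording
  subseed <- matrix(sample.int(.Machine$integer.max - 1L, n_sub * 6L),
                    nrow = n_sub)
  jitter <- runif(n_sub, 0.75, 1.25)  # shared across modalities
  recordings <- list()
  manifest <- list()
  modalities <- c("eeg", "fmri")
  node_tables <- list(eeg = synthetic_node_table(spec$n_eeg_channels, "eeg"),
                      fmri = synthetic_node_table(spec$n_fmri_rois, "fmri"))
  add_recording <- function(ts, subject_id, group, modality, pair_id) {
    rid <- sprintf("%s_%s_%s", subject_id, group, modality)
    recordings[[rid]] <<- ts
    manifest[[length(manifest) + 1L]] <<- data.frame(
      subject_id = subject_id, group = group, modality = modality,
      recording_id = rid, pair_id = pair_id, stringsAsFactors = FALSE)
  }
  for (s in seq_len(n_sub)) {
    paired <- s <= spec$n_paired_subjects
    subject_id <- if (paired) sprintf("P%02d", s)
                  else sprintf("H%02d", s - spec$n_paired_subjects)
    pair_id <- if (paired) subject_id else NA_character_
    for (m in seq_along(modalities)) {
      mod <- modalities[m]
      nn <- if (mod == "eeg") spec$n_eeg_channels else spec$n_fmri_rois
      kk <- if (mod == "eeg") spec$ws_k_eeg else spec$ws_k_fmri
      ns <- if (mod == "eeg") spec$eeg_samples else spec$fmri_volumes
      fs <- if (mod == "eeg") spec$eeg_sampling_rate else 1 / spec$fmri_tr
      labels <- node_tables[[mod]]$label
      g <- generate_small_world_graph(nn, kk, spec$ws_p,
                                      seed = subseed[s, m])
      w <- cluster_mask(nn, spec$cluster_size)
      noise_var <- spec$noise_sd^2
      base_cov <- function(boost) {
        sig <- covariance_from_graph(g, spec$coupling, boost_mask = w,
                                     boost = boost)
        sig + diag(noise_var, nn)
      }
      if (paired) {
        delta_s <- spec$clustering_boost * jitter[s]
        ts1 <- generate_subject_timeseries(base_cov(0), ns, fs, mod,
                                           seed = subseed[s, 2 + m],
                                           subject_id = subject_id,
                                           group = "R1",
                                           node_labels = labels)
        ts2 <- generate_subject_timeseries(base_cov(delta_s), ns, fs, mod,
                                           seed = subseed[s, 4 + m],
                                           subject_id = subject_id,
                                           group = "R2",
                                           node_labels = labels)
        add_recording(ts1, subject_id, "R1", mod, pair_id)
        add_recording(ts2, subject_id, "R2", mod, pair_id)
      } else {
        ts <- generate_subject_timeseries(base_cov(spec$hc_boost), ns, fs,
                                          mod, seed = subseed[s, 2 + m],
                                          subject_id = subject_id,
                                          group = "HC",
                                          node_labels = labels)
        add_recording(ts, subject_id, "HC", mod, pair_id)
      }
    }
  }
  structure(list(recordings = recordings,
                 manifest = do.call(rbind, manifest),
                 node_tables = node_tables, spec = spec),
            class = "mm_cohort")
}

#' Write a synthetic cohort to disk
#'
#' Recordings become nodes-by-samples TSVs with JSON sidecars, the manifest a
#' TSV (subject_id, group, modality, path, pair_id), and node tables TSVs
#' (label, x_mm, y_mm, z_mm, network).
#'
#' @param cohort an `mm_cohort` from [generate_cohort()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "mm_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- cohort$manifest
  manifest$path <- sprintf("%s.tsv", manifest$recording_id)
  for (i in seq_len(nrow(manifest))) {
    write_timeseries_tsv(cohort$recordings[[manifest$recording_id[i]]],
                         file.path(dir, manifest$path[i]))
  }
  write.table(manifest[, c("subject_id", "group", "modality", "path",
                           "pair_id")],
              file.path(dir, "manifest.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  for (mod in names(cohort$node_tables)) {
    write.table(cohort$node_tables[[mod]],
                file.path(dir, sprintf("nodes_%s.tsv", mod)),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(unclass(cohort$spec), file.path(dir, "cohort_spec.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory containing `manifest.tsv`, recording TSVs and node
#'   tables.
#' @return an `mm_cohort`.
#' @export
read_cohort <- function(dir) {
  manifest <- read.table(file.path(dir, "manifest.tsv"), sep = "\t",
                         header = TRUE, stringsAsFactors = FALSE)
  manifest$recording_id <- sub("\\.tsv$", "", manifest$path)
  recordings <- list()
  for (i in seq_len(nrow(manifest))) {
    recordings[[manifest$recording_id[i]]] <-
      read_timeseries_tsv(file.path(dir, manifest$path[i]))
  }
  node_tables <- list()
  for (mod in unique(manifest$modality)) {
    p <- file.path(dir, sprintf("nodes_%s.tsv", mod))
    if (file.exists(p)) {
      node_tables[[mod]] <- read.table(p, sep = "\t", header = TRUE,
                                       stringsAsFactors = FALSE)
    }
  }
  spec_path <- file.path(dir, "cohort_spec.json")
  spec <- if (file.exists(spec_path)) {
    sp <- jsonlite::read_json(spec_path, simplifyVector = TRUE)
    do.call(synthetic_cohort_spec, sp)
  } else NULL
  structure(list(recordings = recordings,
                 manifest = manifest[, c("subject_id", "group", "modality",
                                         "recording_id", "pair_id")],
                 node_tables = node_tables, spec = spec),
            class = "mm_cohort")
}
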