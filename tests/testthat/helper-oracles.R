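# Independent brute-force oracles, kept deliberately naive so they share no
# code path with the implementation they check.

# Triangle-counting clustering coefficient by triple loop.
brute_clustering <- function(adj) {
  n <- nrow(adj)
  cc <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(adj[i, ] == 1)
    k <- length(nb)
    if (k < 2) next
    tri <- 0
    for (a in seq_len(k - 1)) {
      for (b in (a + 1):k) {
        if (adj[nb[a], nb[b]] == 1) tri <- tri + 1
      }
    }
    cc[i] <- 2 * tri / (k * (k - 1))
  }
  list(node_C = cc, C = mean(cc))
}

# Floyd-Warshall characteristic path length over reachable ordered pairs.
brute_path_length <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[adj == 1] <- 1
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  off <- d[row(d) != col(d)]
  list(L = mean(off[is.finite(off)]), fragmented = any(!is.finite(off)))
}

# Benjamini-Hochberg by explicit evaluation of every step-up cutoff.
brute_bh <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  k_star <- 0
  for (k in seq_len(m)) {
    if (p[ord[k]] <= k * q / m) k_star <- k
  }
  mask <- rep(FALSE, m)
  if (k_star > 0) mask[ord[seq_len(k_star)]] <- TRUE
  mask
}

# Erdos-Renyi 0/1 adjacency with at least one edge.
random_adjacency <- function(n, p_edge) {
  repeat {
    adj <- matrix(0L, n, n)
    up <- which(upper.tri(adj))
    on <- up[runif(length(up)) < p_edge]
    adj[on] <- 1L
    adj <- adj + t(adj)
    if (sum(adj) > 0) return(adj)
  }
}

# Minimal mm_timeseries wrapper for unit tests.
make_ts <- function(values, fs = 250, modality = "eeg", ...) {
  time_series_matrix(values, fs, modality, ...)
}

# Small synthetic cohort spec for pipeline-level tests: study-sized group
# structure is tested separately; this keeps per-recording cost low.
small_cohort_spec <- function(seed, n_paired = 5, n_hc = 5, delta = 0.3,
                              eeg_samples = 3000) {
  synthetic_cohort_spec(
    n_paired_subjects = n_paired, n_hc_subjects = n_hc,
    n_eeg_channels = 31, n_fmri_rois = 40, eeg_samples = eeg_samples,
    fmri_volumes = 150, ws_k_fmri = 8, clustering_boost = delta,
    noise_sd = 0.3, seed = seed)
}
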