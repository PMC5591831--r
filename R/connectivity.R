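# Node x node association matrices and their binarization over the sparsity
# grid. Sparsity thresholding keeps the same number of edges for every
# subject, so group comparisons are density-matched.

#' Pearson connectivity matrix of a recording
#'
#' Entry (i, j) is the Pearson correlation of channels i and j over all
#' samples; the diagonal is forced to zero. Constant channels make the
#' correlation undefined and raise an error naming the channel.
#'
#' @param ts an `mm_timeseries` with at least 3 samples.
#' @return an object of class `mm_connectivity`: fields `values` (symmetric,
#'   zero diagonal), `scale` (`"pearson_r"`), `n_samples_used`, `modality`,
#'   `subject_id`, `group`, `node_labels`.
#' @export
correlation_matrix <- function(ts) {
  stopifnot(inherits(ts, "mm_timeseries"))
  if (n_samples(ts) < 3) stop("need at least 3 samples")
  sds <- apply(ts$values, 1, sd)
  if (any(sds == 0)) {
    stop("constant channel(s): ",
         paste(ts$node_labels[sds == 0], collapse = ", "))
  }
  r <- cor(t(ts$values))
  r <- (r + t(r)) / 2           # exact symmetry against FP noise
  diag(r) <- 0
  dimnames(r) <- list(ts$node_labels, ts$node_labels)
  structure(list(values = r, scale = "pearson_r",
                 n_samples_used = n_samples(ts), modality = ts$modality,
                 subject_id = ts$subject_id, group = ts$group,
                 node_labels = ts$node_labels),
            class = "mm_connectivity")
}

#' Fisher z-transform a connectivity matrix
#'
#' Elementwise `z = arctanh(r)`; off-diagonal entries with `|r| >= 1` are
#' clipped to `1 - 1e-7` in magnitude with a warning. The transform is
#' monotone, so binarization by sparsity is unchanged; the z scale is kept
#' for export fidelity.
#'
#' @param cmatrix an `mm_connectivity` on the `pearson_r` scale.
#' @return the matrix on the `fisher_z` scale.
#' @export
fisher_z <- function(cmatrix) {
  stopifnot(inherits(cmatrix, "mm_connectivity"))
  if (cmatrix$scale != "pearson_r") stop("input is already on scale ",
                                         cmatrix$scale)
  r <- cmatrix$values
  off <- row(r) != col(r)
  clip <- off & abs(r) >= 1
  if (any(clip)) {
    warning(sum(clip), " |r| >= 1 entries clipped before arctanh")
    r[clip] <- sign(r[clip]) * (1 - 1e-7)
  }
  z <- atanh(r)
  diag(z) <- 0
  cmatrix$values <- z
  cmatrix$scale <- "fisher_z"
  cmatrix
}

#' The default sparsity grid
#'
#' 0.11 to 0.45 in steps of 0.01 (35 levels) — the range over which
#' thresholded networks remain estimable for small-worldness while avoiding
#' excess fragmentation at sparse thresholds.
#'
#' @param from,to,by grid limits and step.
#' @return strictly increasing numeric vector.
#' @export
sparsity_grid <- function(from = 0.11, to = 0.45, by = 0.01) {
  g <- round(seq(from, to, by = by), 10)
  if (any(diff(g) <= 0)) stop("grid must be strictly increasing")
  g
}

# Edge ranking shared by all sparsity levels: strength descending, ties
# broken lexicographically by (min-node, max-node) so every run selects
# identical edge sets.
rank_edges <- function(values, strength = c("absolute", "positive")) {
  strength <- match.arg(strength)
  n <- nrow(values)
  iu <- which(upper.tri(values), arr.ind = TRUE)
  s <- values[upper.tri(values)]
  s <- if (strength == "absolute") abs(s) else s
  ord <- order(-s, iu[, 1], iu[, 2])
  list(i = iu[ord, 1], j = iu[ord, 2], strength = s[ord], n = n)
}

binary_graph_from_ranked <- function(ranked, m_keep, requested_S) {
  n <- ranked$n
  m_possible <- n * (n - 1) / 2
  adj <- matrix(0L, n, n)
  if (m_keep > 0) {
    idx <- seq_len(m_keep)
    adj[cbind(ranked$i[idx], ranked$j[idx])] <- 1L
    adj[cbind(ranked$j[idx], ranked$i[idx])] <- 1L
  }
  structure(list(adjacency = adj,
                 sparsity = m_keep / m_possible,
                 requested_sparsity = requested_S,
                 source_threshold = if (m_keep > 0)
                   ranked$strength[m_keep] else NA_real_,
                 n_edges = m_keep),
            class = "mm_binary_graph")
}

#' Binarize a connectivity matrix at a target sparsity
#'
#' Keeps exactly `round(S * N * (N - 1) / 2)` strongest edges. Edge strength
#' is the absolute association by default (`|r|` or `|z|`; set
#' `strength = "positive"` to rank signed values). Exact ties at the cut are
#' broken lexicographically by (min-node, max-node) index, so the edge count
#' is exact and runs are deterministic.
#'
#' @param cmatrix an `mm_connectivity` (either scale).
#' @param S target sparsity in (0, 1]: the fraction of possible edges kept.
#' @param strength `"absolute"` (default) or `"positive"`.
#' @return an `mm_binary_graph`: `adjacency` (0/1, zero diagonal),
#'   `sparsity` (realized), `requested_sparsity`, `source_threshold` (the
#'   strength of the weakest retained edge), `n_edges`.
#' @export
threshold_by_sparsity <- function(cmatrix, S,
                                  strength = c("absolute", "positive")) {
  stopifnot(inherits(cmatrix, "mm_connectivity"))
  if (!(S > 0 && S <= 1)) stop("S must lie in (0, 1]")
  ranked <- rank_edges(cmatrix$values, strength)
  n <- ranked$n
  m_possible <- n * (n - 1) / 2
  m_keep <- round(S * m_possible)
  n_nonzero <- sum(ranked$strength > 0)
  if (m_keep > n_nonzero) {
    warning(sprintf(paste0("requested %d edges but only %d nonzero ",
                           "strengths; realized sparsity %.4f"),
                    m_keep, n_nonzero, n_nonzero / m_possible))
    m_keep <- n_nonzero
  }
  g <- binary_graph_from_ranked(ranked, m_keep, S)
  g$node_labels <- cmatrix$node_labels
  g
}

#' Binarize over a whole sparsity grid
#'
#' One binary graph per level, sharing a single edge ranking, so edge sets
#' are nested (the graph at a lower sparsity is a subgraph of the graph at
#' any higher one). Each graph carries a `connected` flag.
#'
#' @param cmatrix an `mm_connectivity`.
#' @param grid sparsity levels (default [sparsity_grid()]).
#' @inheritParams threshold_by_sparsity
#' @return list of `mm_binary_graph`, named by sparsity level.
#' @export
binarize_over_grid <- function(cmatrix, grid = sparsity_grid(),
                               strength = c("absolute", "positive")) {
  stopifnot(inherits(cmatrix, "mm_connectivity"))
  ranked <- rank_edges(cmatrix$values, strength)
  n <- ranked$n
  m_possible <- n * (n - 1) / 2
  n_nonzero <- sum(ranked$strength > 0)
  out <- list()
  for (S in grid) {
    m_keep <- min(round(S * m_possible), n_nonzero)
    g <- binary_graph_from_ranked(ranked, m_keep, S)
    g$node_labels <- cmatrix$node_labels
    g$connected <- is_connected_adjacency(g$adjacency)
    out[[sprintf("%.2f", S)]] <- g
  }
  out
}

is_connected_adjacency <- function(adj) {
  n <- nrow(adj)
  if (n == 0) return(TRUE)
  seen <- logical(n)
  frontier <- 1L
  seen[1L] <- TRUE
  while (length(frontier) > 0) {
    nxt <- which(colSums(adj[frontier, , drop = FALSE] > 0) > 0 & !seen)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  all(seen)
}
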