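# Raw and null-normalized small-world metrics. Clustering, BFS path length
# and degree-preserving rewiring run in compiled code (src/graphops.cpp);
# this file owns the normalization, the sparsity sweep and the per-node
# summaries.

as_adjacency <- function(graph) {
  adj <- if (inherits(graph, c("mm_binary_graph", "mm_ground_truth_graph"))) {
    graph$adjacency
  } else {
    as.matrix(graph)
  }
  storage.mode(adj) <- "integer"
  if (nrow(adj) != ncol(adj)) stop("adjacency must be square")
  if (any(diag(adj) != 0L)) stop("adjacency must have a zero diagonal")
  if (!identical(adj, t(adj))) stop("adjacency must be symmetric")
  if (!all(adj %in% c(0L, 1L))) stop("adjacency must be 0/1")
  adj
}

#' Binary clustering coefficient
#'
#' Watts-Strogatz definition: `node_C(i) = 2 t(i) / (k(i) (k(i) - 1))` with
#' `t(i)` the number of triangles through node i; nodes of degree < 2 get 0.
#' The graph-level `C` is the unweighted mean over all nodes.
#'
#' @param graph an `mm_binary_graph`, `mm_ground_truth_graph` or 0/1
#'   adjacency matrix.
#' @return list with `node_C` (per-node vector) and `C` (mean).
#' @export
clustering_coefficient <- function(graph) {
  adj <- as_adjacency(graph)
  node_C <- cpp_local_clustering(adj)
  list(node_C = node_C, C = mean(node_C))
}

#' Characteristic path length
#'
#' Mean BFS shortest-path length over all reachable ordered node pairs.
#' Unreachable pairs are excluded from the mean and set `fragmented = TRUE`,
#' so sparse thresholds remain estimable without infinite distances.
#'
#' @inheritParams clustering_coefficient
#' @return list with `L` and `fragmented`.
#' @export
characteristic_path_length <- function(graph) {
  adj <- as_adjacency(graph)
  if (nrow(adj) < 2) stop("need at least 2 nodes")
  cpp_path_length(adj)
}

#' Degree-preserving random reference graph
#'
#' Maslov-Sneppen randomization: repeated double-edge swaps that keep every
#' node's degree while destroying topology. Swap attempts that would create a
#' self-loop or duplicate edge are skipped and counted. Graphs with fewer
#' than two edges (no legal swap) are returned unchanged with a flag.
#'
#' @inheritParams clustering_coefficient
#' @param swaps_per_edge attempted swaps per edge (default 10).
#' @param seed optional integer seed; omit to draw from the current RNG
#'   stream.
#' @return an `mm_binary_graph` with attributes `swap_attempts`,
#'   `swap_failed` and `no_swap_possible`.
#' @export
random_reference <- function(graph, swaps_per_edge = 10, seed = NULL) {
  adj <- as_adjacency(graph)
  if (!is.null(seed)) set.seed(as.integer(as.numeric(seed) %% 2147483647))
  res <- cpp_rewire(adj, as.integer(swaps_per_edge))
  n <- nrow(adj)
  m <- sum(adj) / 2
  out <- structure(list(adjacency = res$adjacency,
                        sparsity = if (n > 1) m / (n * (n - 1) / 2) else 0,
                        requested_sparsity = NA_real_,
                        source_threshold = NA_real_, n_edges = m),
                   class = "mm_binary_graph")
  attr(out, "swap_attempts") <- res$attempts
  attr(out, "swap_failed") <- res$failed
  attr(out, "no_swap_possible") <- res$attempts == 0
  out
}

#' Null-normalized small-world metrics of one graph
#'
#' Computes C and L of the graph, the means of both over an ensemble of
#' `n_null` degree-matched random references (one shared ensemble for both),
#' and the normalized metrics `gamma = C / C_rand`, `lambda = L / L_rand`,
#' `sigma = gamma / lambda`. Ensemble member i uses `seed + i`.
#'
#' @inheritParams clustering_coefficient
#' @param n_null ensemble size (default 100).
#' @param swaps_per_edge swaps per edge for each reference.
#' @param seed integer seed for the ensemble.
#' @param sparsity optional sparsity level stored in the result.
#' @return an object of class `mm_graph_metrics`: `C`, `node_C`, `L`,
#'   `C_rand`, `L_rand`, `C_rand_sd`, `L_rand_sd`, `node_C_rand` (per-node
#'   null means), `gamma`, `lambda`, `sigma`, `n_null`, `fragmented`,
#'   `sparsity`.
#' @export
normalized_metrics <- function(graph, n_null = 100, swaps_per_edge = 10,
                               seed = 1L, sparsity = NA_real_) {
  if (n_null < 1) stop("n_null must be at least 1")
  adj <- as_adjacency(graph)
  cc <- clustering_coefficient(adj)
  pl <- characteristic_path_length(adj)
  n <- nrow(adj)
  null_C <- numeric(n_null)
  null_L <- numeric(n_null)
  node_C_rand <- matrix(0, n_null, n)
  frag_null <- FALSE
  for (i in seq_len(n_null)) {
    ref <- random_reference(adj, swaps_per_edge,
                            seed = (as.numeric(seed) + i) %% 2147483647)
    ncc <- clustering_coefficient(ref$adjacency)
    npl <- characteristic_path_length(ref$adjacency)
    null_C[i] <- ncc$C
    node_C_rand[i, ] <- ncc$node_C
    null_L[i] <- npl$L
    frag_null <- frag_null || npl$fragmented
  }
  C_rand <- mean(null_C)
  L_rand <- mean(null_L)
  if (C_rand == 0) {
    stop("degenerate null ensemble: mean null clustering is 0, ",
         "gamma undefined")
  }
  gamma <- cc$C / C_rand
  lambda <- pl$L / L_rand
  structure(list(C = cc$C, node_C = cc$node_C, L = pl$L,
                 C_rand = C_rand, L_rand = L_rand,
                 C_rand_sd = sd(null_C), L_rand_sd = sd(null_L),
                 node_C_rand = colMeans(node_C_rand),
                 gamma = gamma, lambda = lambda, sigma = gamma / lambda,
                 n_null = n_null, fragmented = pl$fragmented,
                 fragmented_null = frag_null, sparsity = sparsity),
            class = "mm_graph_metrics")
}

#' Small-world curve of one recording over the sparsity grid
#'
#' Binarizes the connectivity matrix at every grid level and computes
#' null-normalized metrics per level. Per-node clustering (raw and null
#' means) is retained for the node-level summary.
#'
#' @param cmatrix an `mm_connectivity`.
#' @param grid sparsity levels (default [sparsity_grid()]).
#' @param n_null null-ensemble size per level.
#' @param seed integer seed; level j's ensemble is seeded from
#'   `seed + (j - 1) * (n_null + 1)` so levels do not share streams.
#' @param swaps_per_edge swaps per edge per reference.
#' @inheritParams threshold_by_sparsity
#' @return an object of class `mm_smallworld_curve`: `table` (data.frame
#'   with sparsity, C, L, C_rand, L_rand, gamma, lambda, sigma, fragmented,
#'   connected, n_edges), `node_C` and `node_C_rand` (levels x nodes
#'   matrices), plus subject metadata.
#' @export
metrics_over_sparsity <- function(cmatrix, grid = sparsity_grid(),
                                  n_null = 100, seed = 1L,
                                  swaps_per_edge = 10,
                                  strength = c("absolute", "positive")) {
  stopifnot(inherits(cmatrix, "mm_connectivity"))
  graphs <- binarize_over_grid(cmatrix, grid, strength)
  n <- nrow(cmatrix$values)
  rows <- list()
  node_C <- matrix(NA_real_, length(grid), n)
  node_C_rand <- matrix(NA_real_, length(grid), n)
  for (j in seq_along(grid)) {
    g <- graphs[[j]]
    seed_j <- (as.numeric(seed) + (j - 1) * (n_null + 1)) %% 2147483647
    m <- normalized_metrics(g, n_null = n_null, swaps_per_edge = swaps_per_edge,
                            seed = seed_j, sparsity = grid[j])
    node_C[j, ] <- m$node_C
    node_C_rand[j, ] <- m$node_C_rand
    rows[[j]] <- data.frame(sparsity = grid[j], C = m$C, L = m$L,
                            C_rand = m$C_rand, L_rand = m$L_rand,
                            gamma = m$gamma, lambda = m$lambda,
                            sigma = m$sigma, fragmented = m$fragmented,
                            connected = g$connected, n_edges = g$n_edges)
  }
  colnames(node_C) <- colnames(node_C_rand) <- cmatrix$node_labels
  structure(list(table = do.call(rbind, rows), node_C = node_C,
                 node_C_rand = node_C_rand, grid = grid,
                 subject_id = cmatrix$subject_id, group = cmatrix$group,
                 modality = cmatrix$modality,
                 band = attr(cmatrix, "band") %||% NA_character_,
                 n_null = n_null),
            class = "mm_smallworld_curve")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-node normalized clustering summary of a recording
#'
#' One scalar per node: the mean over the sparsity grid of
#' `node_C(i) / node_C_rand(i)` (the per-node analogue of gamma). Levels
#' where the null mean for a node is zero are excluded for that node; nodes
#' with no usable level anywhere get `NA` and are flagged.
#'
#' @param curve an `mm_smallworld_curve` with per-node values retained.
#' @return named numeric vector (one value per node) with attribute
#'   `undefined_nodes`.
#' @export
node_gamma_summary <- function(curve) {
  stopifnot(inherits(curve, "mm_smallworld_curve"))
  ratio <- curve$node_C / curve$node_C_rand
  ratio[curve$node_C_rand == 0] <- NA_real_
  vals <- colMeans(ratio, na.rm = TRUE)
  vals[is.nan(vals)] <- NA_real_
  undef <- names(vals)[is.na(vals)]
  attr(vals, "undefined_nodes") <- undef
  vals
}

#' Long-format export of a small-world curve
#'
#' @param curve an `mm_smallworld_curve`.
#' @return data.frame with columns subject_id, group, modality, band,
#'   sparsity, metric, value.
#' @export
curve_long <- function(curve) {
  stopifnot(inherits(curve, "mm_smallworld_curve"))
  tab <- curve$table
  metrics <- c("C", "L", "gamma", "lambda", "sigma")
  out <- do.call(rbind, lapply(metrics, function(m) {
    data.frame(subject_id = curve$subject_id, group = curve$group,
               modality = curve$modality, band = curve$band,
               sparsity = tab$sparsity, metric = m, value = tab[[m]],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
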