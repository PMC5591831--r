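test_that("clustering matches hand counts on canonical small graphs", {
  k3 <- matrix(1L, 3, 3); diag(k3) <- 0L
  cc <- clustering_coefficient(k3)
  expect_equal(cc$node_C, rep(1, 3))
  expect_equal(cc$C, 1)
  star <- matrix(0L, 4, 4); star[1, 2:4] <- star[2:4, 1] <- 1L
  expect_equal(clustering_coefficient(star)$C, 0)
  # 4-cycle plus diagonal 1-3: per-node 2/3, 1, 2/3, 1 -> C = 5/6
  g <- matrix(0L, 4, 4)
  for (e in list(c(1, 2), c(2, 3), c(3, 4), c(4, 1), c(1, 3))) {
    g[e[1], e[2]] <- g[e[2], e[1]] <- 1L
  }
  cc2 <- clustering_coefficient(g)
  expect_equal(cc2$node_C, c(2 / 3, 1, 2 / 3, 1), tolerance = 1e-12)
  expect_equal(cc2$C, 5 / 6, tolerance = 1e-12)
})

test_that("path length matches hand counts and flags fragmentation", {
  k4 <- matrix(1L, 4, 4); diag(k4) <- 0L
  pl <- characteristic_path_length(k4)
  expect_equal(pl$L, 1)
  expect_false(pl$fragmented)
  path3 <- matrix(0L, 3, 3)
  path3[1, 2] <- path3[2, 1] <- path3[2, 3] <- path3[3, 2] <- 1L
  expect_equal(characteristic_path_length(path3)$L, 4 / 3, tolerance = 1e-12)
  cycle5 <- matrix(0L, 5, 5)
  for (i in 1:5) {
    j <- i %% 5 + 1
    cycle5[i, j] <- cycle5[j, i] <- 1L
  }
  expect_equal(characteristic_path_length(cycle5)$L, 1.5, tolerance = 1e-12)
  # disconnected: unreachable pairs excluded, flag raised
  two_edges <- matrix(0L, 4, 4)
  two_edges[1, 2] <- two_edges[2, 1] <- two_edges[3, 4] <- two_edges[4, 3] <- 1L
  pl2 <- characteristic_path_length(two_edges)
  expect_equal(pl2$L, 1)
  expect_true(pl2$fragmented)
  expect_error(characteristic_path_length(matrix(0L, 3, 3)), "no edges")
})

test_that("metrics agree with brute-force oracles on random small graphs", {
  set.seed(99)
  for (rep in 1:150) {
    n <- sample(3:8, 1)
    adj <- random_adjacency(n, runif(1, 0.2, 0.8))
    expect_equal(clustering_coefficient(adj)$node_C,
                 brute_clustering(adj)$node_C, tolerance = 1e-14)
    got <- characteristic_path_length(adj)
    want <- brute_path_length(adj)
    expect_equal(got$L, want$L, tolerance = 1e-14)
    expect_identical(got$fragmented, want$fragmented)
  }
})

test_that("degree-preserving rewiring keeps degrees and randomizes topology", {
  k3 <- matrix(1L, 3, 3); diag(k3) <- 0L
  ref <- random_reference(k3, 10, seed = 1)
  expect_identical(ref$adjacency, k3)   # no legal swap exists
  set.seed(10)
  for (rep in 1:25) {
    adj <- random_adjacency(sample(5:30, 1), runif(1, 0.1, 0.6))
    ref <- random_reference(adj, 10)
    expect_identical(sort(colSums(ref$adjacency)), sort(colSums(adj)))
    expect_true(all(diag(ref$adjacency) == 0L))
    expect_identical(ref$adjacency, t(ref$adjacency))
  }
  # rewiring destroys lattice clustering
  drops <- vapply(1:10, function(s) {
    g <- generate_small_world_graph(100, 6, 0.05, seed = s)
    c0 <- clustering_coefficient(g)$C
    cr <- clustering_coefficient(random_reference(g, 10, seed = 100 + s)$adjacency)$C
    cr / c0
  }, numeric(1))
  expect_lt(mean(drops), 0.5)
})

test_that("random graphs self-normalize and sigma is gamma over lambda", {
  set.seed(4)
  adj <- random_adjacency(100, 0.3)
  m <- normalized_metrics(adj, n_null = 30, seed = 14)
  expect_gt(m$gamma, 0.9); expect_lt(m$gamma, 1.1)
  expect_gt(m$lambda, 0.95); expect_lt(m$lambda, 1.05)
  expect_identical(m$sigma, m$gamma / m$lambda)
  g <- generate_small_world_graph(100, 6, 0.05, seed = 6)
  mw <- normalized_metrics(g, n_null = 20, seed = 16)
  expect_gt(mw$sigma, 1.5)
  expect_error(normalized_metrics(adj, n_null = 0), "n_null")
})

test_that("sparsity sweep yields one entry per level, invariant to node order", {
  set.seed(21)
  vals <- matrix(rnorm(25 * 200), 25)
  cm <- correlation_matrix(make_ts(vals))
  grid <- sparsity_grid(0.15, 0.35, 0.05)
  curve <- metrics_over_sparsity(cm, grid = grid, n_null = 5, seed = 3)
  expect_identical(nrow(curve$table), length(grid))
  expect_identical(curve$table$sparsity, grid)
  expect_false(any(is.na(curve$table$sigma)))
  # permuting node order leaves every curve value unchanged
  perm <- sample(25)
  cmp <- correlation_matrix(make_ts(vals[perm, ]))
  curve2 <- metrics_over_sparsity(cmp, grid = grid, n_null = 5, seed = 3)
  # raw metrics are exactly isomorphism-invariant
  expect_equal(curve2$table$C, curve$table$C, tolerance = 1e-12)
  expect_equal(curve2$table$L, curve$table$L, tolerance = 1e-12)
  # normalized metrics differ only by null-ensemble sampling noise
  expect_equal(curve2$table$gamma, curve$table$gamma, tolerance = 0.15)
})

test_that("default grid has 35 levels and curves export long format", {
  expect_length(sparsity_grid(), 35)
  set.seed(30)
  cm <- correlation_matrix(make_ts(matrix(rnorm(15 * 150), 15)))
  curve <- metrics_over_sparsity(cm, grid = sparsity_grid(0.2, 0.3, 0.05),
                                 n_null = 4, seed = 2)
  long <- curve_long(curve)
  expect_identical(nrow(long), 3L * 5L)
  expect_setequal(unique(long$metric), c("C", "L", "gamma", "lambda", "sigma"))
})

test_that("a planted small-world subject dominates a density-matched random one", {
  g <- generate_small_world_graph(60, 6, 0.05, seed = 41)
  sig_sw <- covariance_from_graph(g, 0.2)
  er <- random_reference(g$adjacency, 10, seed = 42)   # degree-matched random
  sig_er <- covariance_from_graph(er$adjacency, 0.2)
  grid <- sparsity_grid(0.15, 0.35, 0.02)
  ts_sw <- generate_subject_timeseries(sig_sw, 4000, 250, "eeg", seed = 43)
  ts_er <- generate_subject_timeseries(sig_er, 4000, 250, "eeg", seed = 44)
  c_sw <- metrics_over_sparsity(correlation_matrix(ts_sw), grid = grid,
                                n_null = 8, seed = 45)
  c_er <- metrics_over_sparsity(correlation_matrix(ts_er), grid = grid,
                                n_null = 8, seed = 46)
  expect_true(all(c_sw$table$sigma > c_er$table$sigma))
})

test_that("node gamma summary is the grid mean of per-node ratios", {
  # construct a curve whose nodes are identical to their nulls -> all 1
  fake <- structure(list(
    table = NULL,
    node_C = matrix(c(0.5, 0.4, 0.3, 0.5, 0.4, 0.3), 2, byrow = TRUE,
                    dimnames = list(NULL, c("a", "b", "c"))),
    node_C_rand = matrix(c(0.5, 0.4, 0.3, 0.5, 0.4, 0.3), 2, byrow = TRUE,
                         dimnames = list(NULL, c("a", "b", "c"))),
    grid = c(0.2, 0.3), subject_id = "s", group = "HC", modality = "eeg",
    band = "beta2", n_null = 10), class = "mm_smallworld_curve")
  expect_equal(unname(node_gamma_summary(fake)), c(1, 1, 1),
               ignore_attr = TRUE)
  # nodes isolated in all nulls are NA and flagged
  fake$node_C_rand[, "c"] <- 0
  out <- node_gamma_summary(fake)
  expect_true(is.na(out["c"]))
  expect_identical(attr(out, "undefined_nodes"), "c")
  expect_length(out, 3)
})
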