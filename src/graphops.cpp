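#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// Binary undirected graph kernels. Adjacency is an n x n 0/1 integer matrix,
// symmetric, zero diagonal; callers validate that contract.

// [[Rcpp::export]]
NumericVector cpp_local_clustering(const IntegerMatrix& adj) {
  const int n = adj.nrow();
  std::vector<std::vector<int> > nb(n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (adj(i, j)) nb[i].push_back(j);
  NumericVector cc(n);
  for (int i = 0; i < n; ++i) {
    const int k = (int) nb[i].size();
    if (k < 2) { cc[i] = 0.0; continue; }
    int tri = 0;
    for (int a = 0; a < k; ++a)
      for (int b = a + 1; b < k; ++b)
        if (adj(nb[i][a], nb[i][b])) ++tri;
    cc[i] = 2.0 * tri / ((double) k * (k - 1));
  }
  return cc;
}

// Mean shortest-path length over reachable ordered pairs (BFS from every
// node); unreachable pairs are excluded and flagged as fragmentation.
// [[Rcpp::export]]
List cpp_path_length(const IntegerMatrix& adj) {
  const int n = adj.nrow();
  std::vector<std::vector<int> > nb(n);
  long nedge = 0;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (adj(i, j)) { nb[i].push_back(j); ++nedge; }
  if (nedge == 0)
    stop("characteristic path length undefined: graph has no edges");
  double total = 0.0;
  long npairs = 0;
  bool fragmented = false;
  std::vector<int> dist(n);
  for (int s = 0; s < n; ++s) {
    std::fill(dist.begin(), dist.end(), -1);
    dist[s] = 0;
    std::queue<int> q;
    q.push(s);
    while (!q.empty()) {
      int u = q.front(); q.pop();
      for (size_t a = 0; a < nb[u].size(); ++a) {
        int v = nb[u][a];
        if (dist[v] < 0) { dist[v] = dist[u] + 1; q.push(v); }
      }
    }
    for (int t = 0; t < n; ++t) {
      if (t == s) continue;
      if (dist[t] < 0) fragmented = true;
      else { total += dist[t]; ++npairs; }
    }
  }
  if (npairs == 0)
    stop("characteristic path length undefined: no reachable pairs");
  return List::create(_["L"] = total / npairs, _["fragmented"] = fragmented);
}

// Maslov-Sneppen degree-preserving randomization by double-edge swap.
// Picks two edges (a,b), (c,d) uniformly and rewires to (a,d), (c,b) when
// that creates no loop or multi-edge. Attempts = swaps_per_edge * |E|;
// failed attempts are skipped and counted. Uses R's RNG so results are
// governed by set.seed().
// [[Rcpp::export]]
List cpp_rewire(const IntegerMatrix& adj, const int swaps_per_edge) {
  const int n = adj.nrow();
  std::vector<int> ei, ej;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      if (adj(i, j)) { ei.push_back(i); ej.push_back(j); }
  const int m = (int) ei.size();
  IntegerMatrix out(clone(adj));
  long attempts = (long) swaps_per_edge * m;
  long failed = 0;
  if (m < 2) {
    return List::create(_["adjacency"] = out, _["attempts"] = 0,
                        _["failed"] = 0);
  }
  for (long it = 0; it < attempts; ++it) {
    int e1 = (int) (unif_rand() * m); if (e1 == m) e1 = m - 1;
    int e2 = (int) (unif_rand() * m); if (e2 == m) e2 = m - 1;
    if (e1 == e2) { ++failed; continue; }
    int a = ei[e1], b = ej[e1], c = ei[e2], d = ej[e2];
    // randomly orient the second edge so both pairings are reachable
    if (unif_rand() < 0.5) std::swap(c, d);
    if (a == c || a == d || b == c || b == d) { ++failed; continue; }
    if (out(a, d) || out(c, b)) { ++failed; continue; }
    out(a, b) = out(b, a) = 0;
    out(c, d) = out(d, c) = 0;
    out(a, d) = out(d, a) = 1;
    out(c, b) = out(b, c) = 1;
    ei[e1] = a; ej[e1] = d;
    ei[e2] = c; ej[e2] = b;
  }
  return List::create(_["adjacency"] = out, _["attempts"] = attempts,
                      _["failed"] = failed);
}
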