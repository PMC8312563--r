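#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

// All-pairs hop distances on an unweighted undirected graph by BFS from each
// source. Unreachable pairs come back as R_PosInf so downstream code can use
// is.finite() directly.
// [[Rcpp::export]]
NumericMatrix bfs_distances(const IntegerMatrix& adj) {
  const int n = adj.nrow();
  std::vector<std::vector<int>> nbr(n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (adj(i, j) != 0) nbr[i].push_back(j);

  NumericMatrix d(n, n);
  std::vector<int> dist(n);
  for (int s = 0; s < n; ++s) {
    std::fill(dist.begin(), dist.end(), -1);
    dist[s] = 0;
    std::queue<int> q;
    q.push(s);
    while (!q.empty()) {
      int v = q.front(); q.pop();
      for (int w : nbr[v]) {
        if (dist[w] < 0) { dist[w] = dist[v] + 1; q.push(w); }
      }
    }
    for (int j = 0; j < n; ++j)
      d(s, j) = dist[j] < 0 ? R_PosInf : (double)dist[j];
  }
  return d;
}

// Brandes (2001) accumulation for unweighted graphs. Each unordered
// source-target pair contributes once and endpoints are excluded, i.e. the
// usual undirected convention (ordered-pair accumulation halved).
// [[Rcpp::export]]
NumericVector brandes_betweenness(const IntegerMatrix& adj) {
  const int n = adj.nrow();
  std::vector<std::vector<int>> nbr(n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (adj(i, j) != 0) nbr[i].push_back(j);

  NumericVector bc(n);
  std::vector<int> dist(n);
  std::vector<double> sigma(n), delta(n);
  std::vector<std::vector<int>> pred(n);
  std::vector<int> stack;
  stack.reserve(n);

  for (int s = 0; s < n; ++s) {
    std::fill(dist.begin(), dist.end(), -1);
    std::fill(sigma.begin(), sigma.end(), 0.0);
    std::fill(delta.begin(), delta.end(), 0.0);
    for (int i = 0; i < n; ++i) pred[i].clear();
    stack.clear();

    dist[s] = 0; sigma[s] = 1.0;
    std::queue<int> q;
    q.push(s);
    while (!q.empty()) {
      int v = q.front(); q.pop();
      stack.push_back(v);
      for (int w : nbr[v]) {
        if (dist[w] < 0) { dist[w] = dist[v] + 1; q.push(w); }
        if (dist[w] == dist[v] + 1) { sigma[w] += sigma[v]; pred[w].push_back(v); }
      }
    }
    for (int i = (int)stack.size() - 1; i >= 0; --i) {
      int w = stack[i];
      for (int v : pred[w])
        delta[v] += sigma[v] / sigma[w] * (1.0 + delta[w]);
      if (w != s) bc[w] += delta[w];
    }
  }
  for (int i = 0; i < n; ++i) bc[i] /= 2.0;  // undirected: each pair counted twice
  return bc;
}

// Maslov-Sneppen degree-preserving rewiring: `attempts` candidate double-edge
// swaps (a,b),(c,d) -> (a,d),(c,b); a candidate is rejected (and counted) if
// it would create a self-loop or a duplicate edge. Uses R's RNG so results
// are reproducible under set.seed().
// [[Rcpp::export]]
List double_edge_swap(const IntegerMatrix& adj, int attempts) {
  const int n = adj.nrow();
  IntegerMatrix a = clone(adj);
  std::vector<int> ea, eb;  // edge list, a < b
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      if (a(i, j) != 0) { ea.push_back(i); eb.push_back(j); }
  const int m = (int)ea.size();
  int rejected = 0;
  if (m < 2) {
    return List::create(_["adjacency"] = a, _["n_rejected"] = attempts,
                        _["n_accepted"] = 0);
  }
  GetRNGstate();
  int accepted = 0;
  for (int t = 0; t < attempts; ++t) {
    int e1 = (int)(unif_rand() * m); if (e1 == m) e1 = m - 1;
    int e2 = (int)(unif_rand() * m); if (e2 == m) e2 = m - 1;
    if (e1 == e2) { ++rejected; continue; }
    int u = ea[e1], v = eb[e1], x = ea[e2], y = eb[e2];
    // orient the second edge at random so both pairings are reachable
    if (unif_rand() < 0.5) std::swap(x, y);
    // proposed new edges: (u,y) and (x,v)
    if (u == y || x == v) { ++rejected; continue; }
    if (a(u, y) != 0 || a(x, v) != 0) { ++rejected; continue; }
    a(u, v) = a(v, u) = 0;
    a(x, y) = a(y, x) = 0;
    a(u, y) = a(y, u) = 1;
    a(x, v) = a(v, x) = 1;
    ea[e1] = std::min(u, y); eb[e1] = std::max(u, y);
    ea[e2] = std::min(x, v); eb[e2] = std::max(x, v);
    ++accepted;
  }
  PutRNGstate();
  return List::create(_["adjacency"] = a, _["n_rejected"] = rejected,
                      _["n_accepted"] = accepted);
}
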