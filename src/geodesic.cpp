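#include <Rcpp.h>
#include <queue>
#include <vector>
#include <limits>
using namespace Rcpp;

// All-pairs shortest paths by the Floyd-Warshall recurrence:
//   d_ij^k = w_ij                                  (k = 0)
//   d_ij^k = min(d_ij^{k-1}, d_ik^{k-1} + d_kj^{k-1})  (k > 0)
// Input: dense symmetric weight matrix, R_PosInf where no edge, 0 diagonal.
// Updates in place on a copy; O(N^3) time, O(N^2) memory.
// [[Rcpp::export]]
NumericMatrix cpp_floyd_warshall(NumericMatrix w) {
  int n = w.nrow();
  NumericMatrix d = clone(w);
  for (int k = 0; k < n; ++k) {
    for (int j = 0; j < n; ++j) {
      double dkj = d(k, j);
      if (!R_finite(dkj)) continue;
      for (int i = 0; i < n; ++i) {
        double via = d(i, k) + dkj;
        if (via < d(i, j)) d(i, j) = via;
      }
    }
  }
  return d;
}

// All-pairs shortest paths by repeated single-source Dijkstra with a binary
// heap; the graph is passed in compressed sparse row form (0-based indptr /
// indices / weights over directed arcs; callers pass a symmetric arc set).
// O(N * (E + N) log N) time, suited to sparse k-NN graphs.
// [[Rcpp::export]]
NumericMatrix cpp_dijkstra_all(IntegerVector indptr, IntegerVector indices,
                               NumericVector weights, int n) {
  NumericMatrix d(n, n);
  std::fill(d.begin(), d.end(), R_PosInf);
  typedef std::pair<double, int> pdi;
  std::vector<double> dist(n);
  std::vector<char> done(n);
  for (int s = 0; s < n; ++s) {
    std::fill(dist.begin(), dist.end(),
              std::numeric_limits<double>::infinity());
    std::fill(done.begin(), done.end(), 0);
    std::priority_queue<pdi, std::vector<pdi>, std::greater<pdi> > pq;
    dist[s] = 0.0;
    pq.push(std::make_pair(0.0, s));
    while (!pq.empty()) {
      pdi top = pq.top();
      pq.pop();
      int u = top.second;
      if (done[u]) continue;
      done[u] = 1;
      for (int e = indptr[u]; e < indptr[u + 1]; ++e) {
        int v = indices[e];
        double nd = dist[u] + weights[e];
        if (nd < dist[v]) {
          dist[v] = nd;
          pq.push(std::make_pair(nd, v));
        }
      }
    }
    for (int i = 0; i < n; ++i) d(i, s) = dist[i];
  }
  return d;
}

// Connected components by breadth-first search over the same CSR arcs.
// Returns 1-based component labels.
// [[Rcpp::export]]
IntegerVector cpp_components(IntegerVector indptr, IntegerVector indices,
                             int n) {
  IntegerVector comp(n, 0);
  std::vector<int> stack;
  int label = 0;
  for (int s = 0; s < n; ++s) {
    if (comp[s] != 0) continue;
    ++label;
    comp[s] = label;
    stack.push_back(s);
    while (!stack.empty()) {
      int u = stack.back();
      stack.pop_back();
      for (int e = indptr[u]; e < indptr[u + 1]; ++e) {
        int v = indices[e];
        if (comp[v] == 0) {
          comp[v] = label;
          stack.push_back(v);
        }
      }
    }
  }
  return comp;
}
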