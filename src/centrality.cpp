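#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Shortest-path centralities for simple undirected unweighted graphs.
// Edges are passed as two 0-based endpoint vectors; n is the node count.

static std::vector<std::vector<int>> build_adj(int n, const IntegerVector &from,
                                               const IntegerVector &to) {
  std::vector<std::vector<int>> adj(n);
  int m = from.size();
  for (int e = 0; e < m; ++e) {
    adj[from[e]].push_back(to[e]);
    adj[to[e]].push_back(from[e]);
  }
  return adj;
}

// Brandes accumulation: one BFS per source, dependencies pushed back in
// reverse BFS order. Raw (unnormalized) pair-count scale; each unordered
// pair is visited from both endpoints, hence the final halving.
// [[Rcpp::export]]
NumericVector brandes_betweenness_cpp(int n, IntegerVector from, IntegerVector to) {
  std::vector<std::vector<int>> adj = build_adj(n, from, to);
  NumericVector cb(n);
  std::vector<int> dist(n), queue(n), order;
  std::vector<double> sigma(n), delta(n);
  std::vector<std::vector<int>> pred(n);
  order.reserve(n);

  for (int s = 0; s < n; ++s) {
    std::fill(dist.begin(), dist.end(), -1);
    std::fill(sigma.begin(), sigma.end(), 0.0);
    std::fill(delta.begin(), delta.end(), 0.0);
    for (int i = 0; i < n; ++i) pred[i].clear();
    order.clear();

    int head = 0, tail = 0;
    dist[s] = 0;
    sigma[s] = 1.0;
    queue[tail++] = s;
    while (head < tail) {
      int v = queue[head++];
      order.push_back(v);
      for (size_t j = 0; j < adj[v].size(); ++j) {
        int w = adj[v][j];
        if (dist[w] < 0) {
          dist[w] = dist[v] + 1;
          queue[tail++] = w;
        }
        if (dist[w] == dist[v] + 1) {
          sigma[w] += sigma[v];
          pred[w].push_back(v);
        }
      }
    }
    for (int i = (int)order.size() - 1; i >= 0; --i) {
      int w = order[i];
      for (size_t j = 0; j < pred[w].size(); ++j) {
        int v = pred[w][j];
        delta[v] += sigma[v] / sigma[w] * (1.0 + delta[w]);
      }
      if (w != s) cb[w] += delta[w];
    }
  }
  for (int i = 0; i < n; ++i) cb[i] /= 2.0;
  return cb;
}

// Wasserman-Faust component-scaled closeness:
//   c(v) = (r / (n-1)) * (r / sum of d(v,u) over the r reachable u != v),
// 0 for isolated nodes. Lies in [0,1] and handles disconnected graphs.
// [[Rcpp::export]]
NumericVector closeness_wf_cpp(int n, IntegerVector from, IntegerVector to) {
  std::vector<std::vector<int>> adj = build_adj(n, from, to);
  NumericVector cc(n);
  std::vector<int> dist(n), queue(n);

  for (int s = 0; s < n; ++s) {
    std::fill(dist.begin(), dist.end(), -1);
    int head = 0, tail = 0;
    dist[s] = 0;
    queue[tail++] = s;
    long long sumd = 0;
    long long r = 0;
    while (head < tail) {
      int v = queue[head++];
      if (v != s) {
        sumd += dist[v];
        r += 1;
      }
      for (size_t j = 0; j < adj[v].size(); ++j) {
        int w = adj[v][j];
        if (dist[w] < 0) {
          dist[w] = dist[v] + 1;
          queue[tail++] = w;
        }
      }
    }
    if (r == 0 || n == 1) {
      cc[s] = 0.0;
    } else {
      cc[s] = ((double)r / (double)(n - 1)) * ((double)r / (double)sumd);
    }
  }
  return cc;
}
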