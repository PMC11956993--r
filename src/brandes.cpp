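#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Weighted betweenness centrality (Brandes 2001) on an undirected graph with
// non-negative edge weights interpreted as distances. Each unordered source-
// target pair contributes once; fractional credit is split across tied
// minimum-distance paths. Shortest-path ties are detected with a relative
// tolerance so that equal path lengths assembled from different floating-point
// sums are still recognized as ties.
//
// Zero-weight edges are legal (Dijkstra only requires non-negativity). When a
// zero-weight cycle makes the shortest-path DAG degenerate, predecessor credit
// follows the deterministic settle order of the heap.

static inline bool near_eq(double a, double b) {
  if (!std::isfinite(a) || !std::isfinite(b)) return false;
  double tol = 1e-10 * std::max(1.0, std::max(std::fabs(a), std::fabs(b)));
  return std::fabs(a - b) <= tol;
}

// [[Rcpp::export(name = ".brandesBetweenness")]]
NumericVector brandes_betweenness(int n, IntegerVector from, IntegerVector to,
                                  NumericVector weight, bool normalized) {
  if (from.size() != to.size() || from.size() != weight.size())
    stop("edge vectors must have equal length");
  int m = from.size();
  for (int e = 0; e < m; ++e) {
    if (weight[e] < 0) stop("negative edge distance");
    if (from[e] < 0 || from[e] >= n || to[e] < 0 || to[e] >= n)
      stop("edge endpoint out of range");
  }

  // adjacency lists (undirected)
  std::vector<std::vector<std::pair<int, double> > > adj(n);
  for (int e = 0; e < m; ++e) {
    adj[from[e]].push_back(std::make_pair(to[e], weight[e]));
    adj[to[e]].push_back(std::make_pair(from[e], weight[e]));
  }

  NumericVector bc(n, 0.0);
  const double INF = std::numeric_limits<double>::infinity();

  std::vector<double> dist(n), sigma(n), delta(n);
  std::vector<bool> settled(n);
  std::vector<std::vector<int> > pred(n);
  std::vector<int> order;
  order.reserve(n);

  typedef std::pair<double, int> QItem;  // (distance, node)

  for (int s = 0; s < n; ++s) {
    std::fill(dist.begin(), dist.end(), INF);
    std::fill(sigma.begin(), sigma.end(), 0.0);
    std::fill(settled.begin(), settled.end(), false);
    for (int i = 0; i < n; ++i) pred[i].clear();
    order.clear();

    dist[s] = 0.0;
    sigma[s] = 1.0;
    std::priority_queue<QItem, std::vector<QItem>, std::greater<QItem> > pq;
    pq.push(std::make_pair(0.0, s));

    while (!pq.empty()) {
      int u = pq.top().second;
      pq.pop();
      if (settled[u]) continue;  // lazy deletion
      settled[u] = true;
      order.push_back(u);
      for (size_t k = 0; k < adj[u].size(); ++k) {
        int v = adj[u][k].first;
        if (settled[v]) continue;
        double cand = dist[u] + adj[u][k].second;
        if (near_eq(cand, dist[v])) {
          sigma[v] += sigma[u];
          pred[v].push_back(u);
        } else if (cand < dist[v]) {
          dist[v] = cand;
          sigma[v] = sigma[u];
          pred[v].clear();
          pred[v].push_back(u);
          pq.push(std::make_pair(cand, v));
        }
      }
    }

    // dependency accumulation in reverse settle order
    std::fill(delta.begin(), delta.end(), 0.0);
    for (int i = (int)order.size() - 1; i >= 0; --i) {
      int w = order[i];
      for (size_t k = 0; k < pred[w].size(); ++k) {
        int v = pred[w][k];
        delta[v] += sigma[v] / sigma[w] * (1.0 + delta[w]);
      }
      if (w != s) bc[w] += delta[w];
    }
  }

  // each unordered pair was visited from both endpoints
  for (int i = 0; i < n; ++i) bc[i] /= 2.0;
  if (normalized && n > 2) {
    double scale = 2.0 / ((double)(n - 1) * (double)(n - 2));
    for (int i = 0; i < n; ++i) bc[i] *= scale;
  }
  return bc;
}
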