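#include <Rcpp.h>
#include <queue>
#include <vector>
#include <utility>
#include <cmath>
using namespace Rcpp;

// Multi-source Dijkstra on an 8-connected raster graph.
//
// edge_times: (nrow*ncol) x 8 matrix, column-major cell index; entry (i, k)
// is the expansion time from cell i to its neighbour in direction k
// (offsets dr[k], dc[k]); NA/NaN means no edge (barrier or off-grid).
// origins: 0-based column-major cell indices with distance 0.
// Returns the minimum accumulated time per cell (Inf where unreachable).
// [[Rcpp::export]]
NumericVector grid_dijkstra_cpp(NumericMatrix edge_times, IntegerVector origins,
                                int nrow, int ncol,
                                IntegerVector dr, IntegerVector dc) {
  const int n = nrow * ncol;
  if (edge_times.nrow() != n || edge_times.ncol() != 8)
    stop("edge_times must be (nrow*ncol) x 8");
  NumericVector dist(n, R_PosInf);
  typedef std::pair<double, int> Node;
  std::priority_queue<Node, std::vector<Node>, std::greater<Node> > pq;
  for (int i = 0; i < origins.size(); ++i) {
    int o = origins[i];
    if (o < 0 || o >= n) stop("origin index out of range");
    if (dist[o] > 0.0) {
      dist[o] = 0.0;
      pq.push(Node(0.0, o));
    }
  }
  while (!pq.empty()) {
    Node top = pq.top();
    pq.pop();
    double d = top.first;
    int u = top.second;
    if (d > dist[u]) continue;  // stale entry
    int r = u % nrow, c = u / nrow;
    for (int k = 0; k < 8; ++k) {
      int rr = r + dr[k], cc = c + dc[k];
      if (rr < 0 || rr >= nrow || cc < 0 || cc >= ncol) continue;
      double w = edge_times(u, k);
      if (!std::isfinite(w)) continue;
      int v = cc * nrow + rr;
      double nd = d + w;
      if (nd < dist[v]) {
        dist[v] = nd;
        pq.push(Node(nd, v));
      }
    }
  }
  return dist;
}
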