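#include <Rcpp.h>
#include <queue>
#include <cmath>
using namespace Rcpp;

// Seeded shortest-path propagation (Jones et al. / CellProfiler secondary
// segmentation). Every foreground pixel is assigned the label of the seed
// reachable at minimal accumulated cost, where the step cost between
// 4-adjacent pixels p and q is sqrt((g(p) - g(q))^2 + lambda^2 * d(p,q)^2)
// with d = 1 for 4-connectivity. Multi-source Dijkstra; ties are broken
// deterministically by insertion order (seeds pushed in raster order).

struct Node {
  double cost;
  long serial;
  int idx;
  int label;
};

struct NodeCmp {
  bool operator()(const Node& a, const Node& b) const {
    if (a.cost != b.cost) return a.cost > b.cost;
    return a.serial > b.serial; // FIFO among equal costs => deterministic
  }
};

// [[Rcpp::export]]
IntegerMatrix propagate_labels_cpp(IntegerMatrix seeds, NumericMatrix guide,
                                   LogicalMatrix foreground, double lambda) {
  int nr = seeds.nrow(), nc = seeds.ncol();
  IntegerMatrix out(nr, nc);
  std::vector<double> dist((size_t)nr * nc,
                           std::numeric_limits<double>::infinity());
  std::priority_queue<Node, std::vector<Node>, NodeCmp> pq;
  long serial = 0;

  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      int i = r + c * nr;
      if (seeds[i] > 0) {
        dist[i] = 0.0;
        out[i] = seeds[i];
        pq.push({0.0, serial++, i, seeds[i]});
      }
    }
  }

  const int dr[4] = {-1, 1, 0, 0};
  const int dc[4] = {0, 0, -1, 1};
  while (!pq.empty()) {
    Node nd = pq.top();
    pq.pop();
    if (nd.cost > dist[nd.idx]) continue;
    int r = nd.idx % nr, c = nd.idx / nr;
    for (int k = 0; k < 4; ++k) {
      int r2 = r + dr[k], c2 = c + dc[k];
      if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
      int j = r2 + c2 * nr;
      if (!foreground[j] || seeds[j] > 0) continue;
      double dg = guide[nd.idx] - guide[j];
      double step = std::sqrt(dg * dg + lambda * lambda);
      double nc_cost = nd.cost + step;
      if (nc_cost < dist[j]) {
        dist[j] = nc_cost;
        out[j] = nd.label;
        pq.push({nc_cost, serial++, j, nd.label});
      }
    }
  }
  return out;
}
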