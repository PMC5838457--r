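#include <Rcpp.h>
#include <queue>
#include <tuple>
#include <vector>
using namespace Rcpp;

// Minimum-weight left-to-right path through a gradient-score grid.
//
// Nodes are pixels (row r, column c) admissible under `mask`. Directed edges
// connect (r, c) to (r + dr, c + 1), dr in {-1, 0, 1}, with weight
//   w = 2 - g[a] - g[b] + wmin,
// where g is the [0,1]-normalised dark-to-bright vertical gradient score.
// Virtual zero-weight columns on both sides let the path enter and leave at
// any row; they are implemented as a multi-source / multi-sink search, so a
// path over nc columns accumulates nc - 1 weighted edges.
//
// Priority is lexicographic (dist, col, deeper row first) and relaxation is
// strict, so tie-breaking is deterministic. Preferring the deeper row on
// exact cost ties aligns the detected line with the boundary-row
// convention: after symmetric smoothing the two rows straddling a
// rasterised layer boundary carry identical gradient, and the interface is
// the first row of the brighter (deeper) layer.

// [[Rcpp::export]]
List dijkstra_path_cpp(NumericMatrix g, LogicalMatrix mask, double wmin) {
  const int nr = g.nrow(), nc = g.ncol();
  const size_t nn = (size_t)nr * (size_t)nc;
  std::vector<double> dist(nn, R_PosInf);
  std::vector<int> prev(nn, -1);
  std::vector<char> done(nn, 0);

  // (dist, col, nr - 1 - row): among equal-cost frontier nodes the larger
  // row index pops, and therefore labels successors, first
  typedef std::tuple<double, int, int> QN;
  std::priority_queue<QN, std::vector<QN>, std::greater<QN> > pq;

  for (int r = 0; r < nr; ++r) {
    if (mask(r, 0)) {
      dist[r] = 0.0;
      pq.push(QN(0.0, 0, nr - 1 - r));
    }
  }

  while (!pq.empty()) {
    const double d = std::get<0>(pq.top());
    const int c = std::get<1>(pq.top());
    const int r = nr - 1 - std::get<2>(pq.top());
    pq.pop();
    const size_t id = (size_t)c * nr + r;
    if (done[id]) continue;
    done[id] = 1;
    if (c == nc - 1) continue;
    for (int dr = -1; dr <= 1; ++dr) {
      const int r2 = r + dr;
      if (r2 < 0 || r2 >= nr) continue;
      if (!mask(r2, c + 1)) continue;
      const double w = 2.0 - g(r, c) - g(r2, c + 1) + wmin;
      const size_t id2 = (size_t)(c + 1) * nr + r2;
      if (d + w < dist[id2]) {
        dist[id2] = d + w;
        prev[id2] = (int)id;
        pq.push(QN(dist[id2], c + 1, nr - 1 - r2));
      }
    }
  }

  // endpoint: minimal cost, deeper row on ties (scan keeps the last min)
  int best = -1;
  double bd = R_PosInf;
  for (int r = 0; r < nr; ++r) {
    const size_t id = (size_t)(nc - 1) * nr + r;
    if (dist[id] <= bd) {
      bd = dist[id];
      best = (int)id;
    }
  }
  if (best < 0 || !R_FINITE(bd))
    return List::create(_["feasible"] = false);

  IntegerVector rows(nc);
  int cur = best;
  for (int c = nc - 1; c >= 0; --c) {
    rows[c] = cur % nr + 1; // 1-based for R
    cur = prev[cur];
  }
  return List::create(_["feasible"] = true, _["rows"] = rows,
                      _["cost"] = bd);
}
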