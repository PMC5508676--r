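#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Dijkstra front propagation from a seed pixel over the whole raster.
// node_cost holds the per-unit-length cost of entering each pixel (the
// cost-intensity function already applied); a step into pixel q costs
// node_cost(q) * step_length (1 axial, sqrt(2) diagonal).  The front stops
// only at the image limits, so every pixel ends up with its minimal
// accumulated cost from the seed.
// [[Rcpp::export]]
NumericMatrix cpp_dijkstra(NumericMatrix node_cost, int seed_r, int seed_c,
                           bool diag) {
  const int nr = node_cost.nrow(), nc = node_cost.ncol();
  const int s = (seed_c - 1) * nr + (seed_r - 1); // 1-based input
  std::vector<double> dist((size_t)nr * nc, R_PosInf);
  typedef std::pair<double, int> P;
  std::priority_queue<P, std::vector<P>, std::greater<P> > pq;
  dist[s] = 0.0;
  pq.push(P(0.0, s));
  const int dr[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const double dl[8] = {M_SQRT2, 1, M_SQRT2, 1, 1, M_SQRT2, 1, M_SQRT2};
  while (!pq.empty()) {
    double d = pq.top().first;
    int u = pq.top().second;
    pq.pop();
    if (d > dist[u]) continue;
    int ur = u % nr, uc = u / nr;
    for (int k = 0; k < 8; k++) {
      if (!diag && dl[k] > 1.0) continue;
      int vr = ur + dr[k], vc = uc + dc[k];
      if (vr < 0 || vr >= nr || vc < 0 || vc >= nc) continue;
      int v = vc * nr + vr;
      double nd = d + node_cost(vr, vc) * dl[k];
      if (nd < dist[v]) {
        dist[v] = nd;
        pq.push(P(nd, v));
      }
    }
  }
  NumericMatrix out(nr, nc);
  std::copy(dist.begin(), dist.end(), out.begin());
  return out;
}

static inline int at(const LogicalMatrix &m, int r, int c) {
  if (r < 0 || r >= m.nrow() || c < 0 || c >= m.ncol()) return 0;
  return m(r, c) ? 1 : 0;
}

// Zhang-Suen morphological thinning of a binary mask to a 1-px skeleton.
// [[Rcpp::export]]
LogicalMatrix cpp_thin(LogicalMatrix mask) {
  LogicalMatrix m = clone(mask);
  const int nr = m.nrow(), nc = m.ncol();
  bool changed = true;
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; pass++) {
      std::vector<std::pair<int, int> > del;
      for (int r = 0; r < nr; r++) {
        for (int c = 0; c < nc; c++) {
          if (!m(r, c)) continue;
          int p2 = at(m, r - 1, c),     p3 = at(m, r - 1, c + 1);
          int p4 = at(m, r, c + 1),     p5 = at(m, r + 1, c + 1);
          int p6 = at(m, r + 1, c),     p7 = at(m, r + 1, c - 1);
          int p8 = at(m, r, c - 1),     p9 = at(m, r - 1, c - 1);
          int bp = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
          if (bp < 2 || bp > 6) continue;
          int seq[9] = {p2, p3, p4, p5, p6, p7, p8, p9, p2};
          int ap = 0;
          for (int k = 0; k < 8; k++)
            if (seq[k] == 0 && seq[k + 1] == 1) ap++;
          if (ap != 1) continue;
          if (pass == 0) {
            if (p2 * p4 * p6 != 0 || p4 * p6 * p8 != 0) continue;
          } else {
            if (p2 * p4 * p8 != 0 || p2 * p6 * p8 != 0) continue;
          }
          del.push_back(std::make_pair(r, c));
        }
      }
      if (!del.empty()) changed = true;
      for (size_t i = 0; i < del.size(); i++)
        m(del[i].first, del[i].second) = false;
    }
  }
  return m;
}
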