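#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
#include <limits>
using namespace Rcpp;

// First-order fast marching on a triangle mesh: front propagation solving
// the eikonal equation |grad T| = 1 with unit speed, giving geodesic
// distance from the source set. Per-triangle two-point update: the front is
// modelled as a planar wave crossing the triangle, fixed by the accepted
// values at the two known vertices; the update vertex gets the wave's
// arrival time. When no causal planar wave exists (including the obtuse
// configuration at the update vertex) the update falls back to the one-point
// (edge) value, which equals Dijkstra's relaxation and keeps the field
// bounded above by the edge-graph distance.

static double two_point_update(double a2, double b2, double c,
                               double TA, double TB) {
  // local frame: A=(0,0), B=(c,0), C=(cx,cy), cy>0
  // a2=|CB|^2, b2=|CA|^2, c=|AB|
  double cx = (b2 + c * c - a2) / (2.0 * c);
  double cy2 = b2 - cx * cx;
  if (cy2 <= 0.0) return INFINITY;  // degenerate triangle
  double cy = std::sqrt(cy2);
  // obtuse angle at C (dot(A-C, B-C) < 0): fall back to one-point update
  if ((-cx) * (c - cx) + cy2 < 0.0) return INFINITY;
  double n1 = (TB - TA) / c;
  if (std::fabs(n1) >= 1.0) return INFINITY;  // no unit-speed planar wave
  double n2 = std::sqrt(1.0 - n1 * n1);
  double TC = TA + n1 * cx + n2 * cy;
  // causality: characteristic from C back along the gradient must cross
  // the open segment AB
  double t = cy / n2;
  double xhit = cx - t * n1;
  if (xhit <= 0.0 || xhit >= c) return INFINITY;
  if (TC < TA || TC < TB) return INFINITY;
  return TC;
}

// [[Rcpp::export]]
NumericVector cpp_fmm(NumericMatrix V, IntegerMatrix F,
                      IntegerVector sources) {
  const double INF = std::numeric_limits<double>::infinity();
  int nv = V.nrow(), nf = F.nrow();

  // vertex -> incident faces (CSR)
  std::vector<int> deg(nv + 1, 0);
  for (int f = 0; f < nf; ++f)
    for (int k = 0; k < 3; ++k) deg[F(f, k)]++;
  std::vector<int> off(nv + 2, 0);
  for (int v = 1; v <= nv; ++v) off[v + 1] = off[v] + deg[v];
  std::vector<int> vfaces(off[nv + 1]);
  std::vector<int> cur(nv + 1, 0);
  for (int f = 0; f < nf; ++f)
    for (int k = 0; k < 3; ++k) {
      int v = F(f, k);
      vfaces[off[v] + cur[v]++] = f;
    }

  auto dist2 = [&](int a, int b) {
    double dx = V(a - 1, 0) - V(b - 1, 0);
    double dy = V(a - 1, 1) - V(b - 1, 1);
    double dz = V(a - 1, 2) - V(b - 1, 2);
    return dx * dx + dy * dy + dz * dz;
  };

  std::vector<double> T(nv + 1, INF);
  std::vector<char> accepted(nv + 1, 0);
  typedef std::pair<double, int> QE;
  std::priority_queue<QE, std::vector<QE>, std::greater<QE>> pq;
  for (int i = 0; i < sources.size(); ++i) {
    T[sources[i]] = 0.0;
    pq.push(QE(0.0, sources[i]));
  }

  while (!pq.empty()) {
    QE top = pq.top(); pq.pop();
    int u = top.second;
    if (accepted[u]) continue;
    accepted[u] = 1;
    // relax every non-accepted vertex of every triangle incident to u
    for (int k = off[u]; k < off[u + 1]; ++k) {
      int f = vfaces[k];
      int tri[3] = {F(f, 0), F(f, 1), F(f, 2)};
      for (int j = 0; j < 3; ++j) {
        int C = tri[j];
        if (accepted[C]) continue;
        int A = tri[(j + 1) % 3], B = tri[(j + 2) % 3];
        double cand = INF;
        if (accepted[A])
          cand = std::min(cand, T[A] + std::sqrt(dist2(C, A)));
        if (accepted[B])
          cand = std::min(cand, T[B] + std::sqrt(dist2(C, B)));
        if (accepted[A] && accepted[B]) {
          double c2 = dist2(A, B);
          if (c2 > 0.0) {
            double tp = two_point_update(dist2(C, B), dist2(C, A),
                                         std::sqrt(c2), T[A], T[B]);
            cand = std::min(cand, tp);
          }
        }
        if (cand < T[C]) {
          T[C] = cand;
          pq.push(QE(cand, C));
        }
      }
    }
  }

  NumericVector out(nv);
  for (int v = 1; v <= nv; ++v) out[v - 1] = T[v];
  return out;
}
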