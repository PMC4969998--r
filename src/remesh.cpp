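#include <Rcpp.h>
#include <vector>
#include <array>
#include <unordered_map>
#include <unordered_set>
#include <cmath>
#include <cstdint>
#include <algorithm>
#include <limits>
using namespace Rcpp;

// Isotropic remeshing toward a target mean edge length: iterated long-edge
// split, short-edge collapse, valence-equalising flips and tangential
// relaxation, with relaxed vertices projected back onto the input surface
// (closest point on the original triangles, uniform-grid accelerated).
// Boundary vertices move only by boundary-edge collapse, so boundary loop
// count and closedness are preserved; collapses respect the link condition
// so the mesh stays manifold.

typedef std::array<double, 3> P3;
typedef std::array<int, 3> Tri;

static inline P3 sub(const P3 &a, const P3 &b) {
  return {a[0] - b[0], a[1] - b[1], a[2] - b[2]};
}
static inline P3 add(const P3 &a, const P3 &b) {
  return {a[0] + b[0], a[1] + b[1], a[2] + b[2]};
}
static inline P3 mul(const P3 &a, double s) {
  return {a[0] * s, a[1] * s, a[2] * s};
}
static inline double dot(const P3 &a, const P3 &b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}
static inline P3 cross(const P3 &a, const P3 &b) {
  return {a[1] * b[2] - a[2] * b[1],
          a[2] * b[0] - a[0] * b[2],
          a[0] * b[1] - a[1] * b[0]};
}
static inline double norm2(const P3 &a) { return dot(a, a); }
static inline double dist2(const P3 &a, const P3 &b) { return norm2(sub(a, b)); }

// closest point on triangle abc to p (Ericson, Real-Time Collision Detection)
static P3 closest_on_tri(const P3 &p, const P3 &a, const P3 &b, const P3 &c) {
  P3 ab = sub(b, a), ac = sub(c, a), ap = sub(p, a);
  double d1 = dot(ab, ap), d2 = dot(ac, ap);
  if (d1 <= 0 && d2 <= 0) return a;
  P3 bp = sub(p, b);
  double d3 = dot(ab, bp), d4 = dot(ac, bp);
  if (d3 >= 0 && d4 <= d3) return b;
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    double v = d1 / (d1 - d3);
    return add(a, mul(ab, v));
  }
  P3 cp = sub(p, c);
  double d5 = dot(ab, cp), d6 = dot(ac, cp);
  if (d6 >= 0 && d5 <= d6) return c;
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    double w = d2 / (d2 - d6);
    return add(a, mul(ac, w));
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    return add(b, mul(sub(c, b), w));
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  return add(a, add(mul(ab, v), mul(ac, w)));
}

// uniform grid over the original triangles for closest-point queries
struct TriGrid {
  std::vector<P3> V;
  std::vector<Tri> F;
  P3 lo, hi;
  double h;
  int nx, ny, nz;
  std::vector<std::vector<int>> cells;

  void build(const std::vector<P3> &Vin, const std::vector<Tri> &Fin) {
    V = Vin; F = Fin;
    lo = {1e300, 1e300, 1e300}; hi = {-1e300, -1e300, -1e300};
    for (const P3 &p : V)
      for (int k = 0; k < 3; ++k) {
        lo[k] = std::min(lo[k], p[k]);
        hi[k] = std::max(hi[k], p[k]);
      }
    double diag = std::sqrt(dist2(lo, hi));
    double tot = 0;
    for (const Tri &t : F)
      tot += std::sqrt(dist2(V[t[0]], V[t[1]]));
    double medge = tot / std::max<size_t>(1, F.size());
    h = std::max(2.0 * medge, diag / 64.0);
    if (h <= 0) h = 1.0;
    nx = std::max(1, (int)std::floor((hi[0] - lo[0]) / h) + 1);
    ny = std::max(1, (int)std::floor((hi[1] - lo[1]) / h) + 1);
    nz = std::max(1, (int)std::floor((hi[2] - lo[2]) / h) + 1);
    cells.assign((size_t)nx * ny * nz, {});
    for (int f = 0; f < (int)F.size(); ++f) {
      P3 tlo = {1e300, 1e300, 1e300}, thi = {-1e300, -1e300, -1e300};
      for (int k = 0; k < 3; ++k) {
        const P3 &p = V[F[f][k]];
        for (int d = 0; d < 3; ++d) {
          tlo[d] = std::min(tlo[d], p[d]);
          thi[d] = std::max(thi[d], p[d]);
        }
      }
      int i0 = cl(tlo[0], 0, nx), i1 = cl(thi[0], 0, nx);
      int j0 = cl(tlo[1], 1, ny), j1 = cl(thi[1], 1, ny);
      int k0 = cl(tlo[2], 2, nz), k1 = cl(thi[2], 2, nz);
      for (int i = i0; i <= i1; ++i)
        for (int j = j0; j <= j1; ++j)
          for (int k = k0; k <= k1; ++k)
            cells[idx(i, j, k)].push_back(f);
    }
  }
  int cl(double x, int d, int n) const {
    int i = (int)std::floor((x - lo[d]) / h);
    return std::max(0, std::min(n - 1, i));
  }
  size_t idx(int i, int j, int k) const {
    return ((size_t)i * ny + j) * nz + k;
  }
  P3 project(const P3 &p) const {
    int ci = cl(p[0], 0, nx), cj = cl(p[1], 1, ny), ck = cl(p[2], 2, nz);
    double best = std::numeric_limits<double>::infinity();
    P3 bestp = p;
    int maxr = std::max(nx, std::max(ny, nz));
    for (int r = 0; r <= maxr; ++r) {
      if (best < std::pow(std::max(0, r - 1) * h, 2) && r > 1) break;
      for (int i = std::max(0, ci - r); i <= std::min(nx - 1, ci + r); ++i)
        for (int j = std::max(0, cj - r); j <= std::min(ny - 1, cj + r); ++j)
          for (int k = std::max(0, ck - r); k <= std::min(nz - 1, ck + r); ++k) {
            if (std::max({std::abs(i - ci), std::abs(j - cj),
                          std::abs(k - ck)}) != r)
              continue;  // shell only
            for (int f : cells[idx(i, j, k)]) {
              P3 q = closest_on_tri(p, V[F[f][0]], V[F[f][1]], V[F[f][2]]);
              double d2 = dist2(p, q);
              if (d2 < best) { best = d2; bestp = q; }
            }
          }
    }
    return bestp;
  }
};

struct Mesh {
  std::vector<P3> V;
  std::vector<Tri> F;

  double mean_edge() const {
    std::unordered_set<uint64_t> seen;
    double tot = 0; size_t n = 0;
    uint64_t nv = V.size() + 1;
    for (const Tri &t : F)
      for (int e = 0; e < 3; ++e) {
        int a = t[e], b = t[(e + 1) % 3];
        uint64_t key = (uint64_t)std::min(a, b) * nv + std::max(a, b);
        if (seen.insert(key).second) {
          tot += std::sqrt(dist2(V[a], V[b]));
          ++n;
        }
      }
    return n ? tot / n : 0.0;
  }
};

static uint64_t ekey(int a, int b, uint64_t nv) {
  return (uint64_t)std::min(a, b) * nv + std::max(a, b);
}

static void split_long_edges(Mesh &m, double lmax) {
  uint64_t nv = m.V.size() + 1;
  std::unordered_map<uint64_t, int> mid;  // edge -> midpoint vertex
  for (const Tri &t : m.F)
    for (int e = 0; e < 3; ++e) {
      int a = t[e], b = t[(e + 1) % 3];
      uint64_t k = ekey(a, b, nv);
      if (mid.count(k)) continue;
      if (dist2(m.V[a], m.V[b]) > lmax * lmax) {
        m.V.push_back(mul(add(m.V[a], m.V[b]), 0.5));
        mid[k] = (int)m.V.size() - 1;
      }
    }
  if (mid.empty()) return;
  std::vector<Tri> out;
  out.reserve(m.F.size() * 2);
  for (const Tri &t : m.F) {
    int v0 = t[0], v1 = t[1], v2 = t[2];
    int m01 = -1, m12 = -1, m20 = -1;
    auto it = mid.find(ekey(v0, v1, nv)); if (it != mid.end()) m01 = it->second;
    it = mid.find(ekey(v1, v2, nv)); if (it != mid.end()) m12 = it->second;
    it = mid.find(ekey(v2, v0, nv)); if (it != mid.end()) m20 = it->second;
    int ns = (m01 >= 0) + (m12 >= 0) + (m20 >= 0);
    // rotate so canonical cases apply
    while (ns == 1 && m01 < 0) {
      int tv = v0; v0 = v1; v1 = v2; v2 = tv;
      int tm = m01; m01 = m12; m12 = m20; m20 = tm;
    }
    while (ns == 2 && !(m01 >= 0 && m12 >= 0)) {
      int tv = v0; v0 = v1; v1 = v2; v2 = tv;
      int tm = m01; m01 = m12; m12 = m20; m20 = tm;
    }
    if (ns == 0) {
      out.push_back({v0, v1, v2});
    } else if (ns == 1) {
      out.push_back({v0, m01, v2});
      out.push_back({m01, v1, v2});
    } else if (ns == 2) {
      out.push_back({v0, m01, v2});
      out.push_back({m01, m12, v2});
      out.push_back({m01, v1, m12});
    } else {
      out.push_back({v0, m01, m20});
      out.push_back({m01, v1, m12});
      out.push_back({m20, m12, v2});
      out.push_back({m01, m12, m20});
    }
  }
  m.F.swap(out);
}

struct Adjacency {
  std::vector<std::vector<int>> vnbr;   // vertex -> neighbour vertices
  std::vector<std::vector<int>> vface;  // vertex -> incident faces
  std::vector<char> boundary;           // boundary vertex flag
  std::unordered_map<uint64_t, std::vector<int>> efaces;  // edge -> faces

  void build(const Mesh &m) {
    int n = m.V.size();
    uint64_t nv = n + 1;
    vnbr.assign(n, {});
    vface.assign(n, {});
    boundary.assign(n, 0);
    efaces.clear();
    for (int f = 0; f < (int)m.F.size(); ++f)
      for (int e = 0; e < 3; ++e) {
        int a = m.F[f][e], b = m.F[f][(e + 1) % 3];
        efaces[ekey(a, b, nv)].push_back(f);
        vface[a].push_back(f);
      }
    for (auto &kv : efaces) {
      int a = (int)(kv.first / nv), b = (int)(kv.first % nv);
      vnbr[a].push_back(b);
      vnbr[b].push_back(a);
      if (kv.second.size() == 1) { boundary[a] = 1; boundary[b] = 1; }
    }
  }
};

static bool face_dead(const Tri &t) {
  return t[0] == t[1] || t[1] == t[2] || t[0] == t[2];
}

static P3 face_normal(const Mesh &m, const Tri &t) {
  return cross(sub(m.V[t[1]], m.V[t[0]]), sub(m.V[t[2]], m.V[t[0]]));
}

static int collapse_short_edges(Mesh &m, double lmin, double lmax) {
  Adjacency adj;
  adj.build(m);
  uint64_t nv = m.V.size() + 1;
  std::vector<char> dirty(m.V.size(), 0);
  int ncollapsed = 0;

  // collect candidate edges, shortest first for stable behaviour
  std::vector<std::pair<double, uint64_t>> cand;
  for (auto &kv : adj.efaces) {
    int a = (int)(kv.first / nv), b = (int)(kv.first % nv);
    double d2 = dist2(m.V[a], m.V[b]);
    if (d2 < lmin * lmin) cand.push_back({d2, kv.first});
  }
  std::sort(cand.begin(), cand.end());

  for (auto &ce : cand) {
    int a = (int)(ce.second / nv), b = (int)(ce.second % nv);
    if (dirty[a] || dirty[b]) continue;
    const std::vector<int> &ef = adj.efaces[ce.second];
    bool eb = ef.size() == 1;            // boundary edge
    bool ab = adj.boundary[a] != 0, bb = adj.boundary[b] != 0;
    if (ab && bb && !eb) continue;       // interior chord between boundary pts
    // collapse target position
    P3 pos;
    if (ab && !bb) pos = m.V[a];
    else if (bb && !ab) pos = m.V[b];
    else pos = mul(add(m.V[a], m.V[b]), 0.5);
    // link condition: common neighbours == opposite vertices of edge faces
    std::unordered_set<int> na(adj.vnbr[a].begin(), adj.vnbr[a].end());
    std::vector<int> common;
    for (int x : adj.vnbr[b]) if (na.count(x)) common.push_back(x);
    if ((int)common.size() != (int)ef.size()) continue;
    // no over-long edges after collapse
    bool ok = true;
    for (int x : adj.vnbr[a])
      if (x != b && dist2(pos, m.V[x]) > lmax * lmax) { ok = false; break; }
    if (ok) for (int x : adj.vnbr[b])
      if (x != a && dist2(pos, m.V[x]) > lmax * lmax) { ok = false; break; }
    if (!ok) continue;
    // no face inversion among surviving incident faces
    P3 olda = m.V[a], oldb = m.V[b];
    std::vector<int> inc = adj.vface[a];
    inc.insert(inc.end(), adj.vface[b].begin(), adj.vface[b].end());
    for (int f : inc) {
      Tri t = m.F[f];
      bool hasa = t[0] == a || t[1] == a || t[2] == a;
      bool hasb = t[0] == b || t[1] == b || t[2] == b;
      if (hasa && hasb) continue;  // dies in collapse
      P3 n0 = face_normal(m, t);
      m.V[a] = pos; m.V[b] = pos;
      Tri t2 = t;
      for (int k = 0; k < 3; ++k) if (t2[k] == b) t2[k] = a;
      P3 n1 = face_normal(m, t2);
      m.V[a] = olda; m.V[b] = oldb;
      if (dot(n0, n1) <= 0) { ok = false; break; }
    }
    if (!ok) continue;
    // apply: merge b into a
    m.V[a] = pos;
    for (int f : adj.vface[b]) {
      for (int k = 0; k < 3; ++k) if (m.F[f][k] == b) m.F[f][k] = a;
      adj.vface[a].push_back(f);
    }
    dirty[a] = 1; dirty[b] = 1;
    ++ncollapsed;
    for (int x : adj.vnbr[a]) dirty[x] = 1;
    for (int x : adj.vnbr[b]) dirty[x] = 1;
    if (eb || (ab && bb)) adj.boundary[a] = 1;
  }

  // drop dead faces, compact vertices
  std::vector<Tri> keep;
  keep.reserve(m.F.size());
  for (const Tri &t : m.F) if (!face_dead(t)) keep.push_back(t);
  m.F.swap(keep);
  std::vector<int> remap(m.V.size(), -1);
  std::vector<P3> nV;
  for (Tri &t : m.F)
    for (int k = 0; k < 3; ++k) {
      if (remap[t[k]] < 0) {
        remap[t[k]] = (int)nV.size();
        nV.push_back(m.V[t[k]]);
      }
      t[k] = remap[t[k]];
    }
  m.V.swap(nV);
  return ncollapsed;
}

static void flip_pass(Mesh &m) {
  Adjacency adj;
  adj.build(m);
  int n = m.V.size();
  uint64_t nv = n + 1;
  std::vector<int> val(n, 0);
  for (int v = 0; v < n; ++v) val[v] = (int)adj.vnbr[v].size();
  std::unordered_set<uint64_t> edges;
  for (auto &kv : adj.efaces) edges.insert(kv.first);
  auto target = [&](int v) { return adj.boundary[v] ? 4 : 6; };

  for (auto &kv : adj.efaces) {
    if (kv.second.size() != 2) continue;
    int f1 = kv.second[0], f2 = kv.second[1];
    Tri t1 = m.F[f1], t2 = m.F[f2];
    if (face_dead(t1) || face_dead(t2)) continue;
    int a = (int)(kv.first / nv), b = (int)(kv.first % nv);
    // earlier flips may have removed this edge from its recorded faces
    auto has = [](const Tri &t, int v) {
      return t[0] == v || t[1] == v || t[2] == v;
    };
    if (!has(t1, a) || !has(t1, b) || !has(t2, a) || !has(t2, b)) continue;
    if (!edges.count(kv.first)) continue;
    // orient so t1 contains a->b
    bool t1ab = false;
    for (int e = 0; e < 3; ++e)
      if (t1[e] == a && t1[(e + 1) % 3] == b) t1ab = true;
    if (!t1ab) { std::swap(f1, f2); std::swap(t1, t2); }
    int c = -1, d = -1;
    for (int k = 0; k < 3; ++k) {
      if (t1[k] != a && t1[k] != b) c = t1[k];
      if (t2[k] != a && t2[k] != b) d = t2[k];
    }
    if (c < 0 || d < 0 || c == d) continue;
    if (edges.count(ekey(c, d, nv))) continue;
    int before = std::abs(val[a] - target(a)) + std::abs(val[b] - target(b)) +
                 std::abs(val[c] - target(c)) + std::abs(val[d] - target(d));
    int after = std::abs(val[a] - 1 - target(a)) +
                std::abs(val[b] - 1 - target(b)) +
                std::abs(val[c] + 1 - target(c)) +
                std::abs(val[d] + 1 - target(d));
    if (after >= before) continue;
    Tri n1 = {c, a, d}, n2 = {d, b, c};
    P3 nn1 = face_normal(m, n1), nn2 = face_normal(m, n2);
    P3 on = add(face_normal(m, t1), face_normal(m, t2));
    if (dot(nn1, on) <= 0 || dot(nn2, on) <= 0) continue;
    double amin = std::min(std::sqrt(norm2(nn1)), std::sqrt(norm2(nn2)));
    if (amin < 1e-12) continue;
    m.F[f1] = n1;
    m.F[f2] = n2;
    edges.erase(ekey(a, b, nv));
    edges.insert(ekey(c, d, nv));
    val[a]--; val[b]--; val[c]++; val[d]++;
  }
}

static void smooth_project(Mesh &m, const TriGrid &grid, double lambda) {
  Adjacency adj;
  adj.build(m);
  int n = m.V.size();
  std::vector<P3> vnorm(n, {0, 0, 0});
  for (const Tri &t : m.F) {
    P3 fn = face_normal(m, t);
    for (int k = 0; k < 3; ++k) vnorm[t[k]] = add(vnorm[t[k]], fn);
  }
  std::vector<P3> out = m.V;
  for (int v = 0; v < n; ++v) {
    if (adj.boundary[v] || adj.vnbr[v].empty()) continue;
    P3 g = {0, 0, 0};
    for (int x : adj.vnbr[v]) g = add(g, m.V[x]);
    g = mul(g, 1.0 / adj.vnbr[v].size());
    P3 d = sub(g, m.V[v]);
    double nn = norm2(vnorm[v]);
    if (nn > 0) {
      P3 un = mul(vnorm[v], 1.0 / std::sqrt(nn));
      d = sub(d, mul(un, dot(d, un)));  // tangential component only
    }
    P3 moved = add(m.V[v], mul(d, lambda));
    out[v] = grid.project(moved);
  }
  m.V.swap(out);
}

// [[Rcpp::export]]
List cpp_remesh(NumericMatrix Vin, IntegerMatrix Fin, double target,
                int max_iter) {
  Mesh m;
  int n = Vin.nrow(), nf = Fin.nrow();
  m.V.resize(n);
  for (int i = 0; i < n; ++i)
    m.V[i] = {Vin(i, 0), Vin(i, 1), Vin(i, 2)};
  m.F.resize(nf);
  for (int f = 0; f < nf; ++f)
    m.F[f] = {Fin(f, 0) - 1, Fin(f, 1) - 1, Fin(f, 2) - 1};

  double me = m.mean_edge();
  bool converged = me >= 0.9 * target && me <= 1.1 * target;
  int used = 0;
  if (!converged) {
    TriGrid grid;
    grid.build(m.V, m.F);
    for (int it = 0; it < max_iter && !converged; ++it) {
      ++used;
      split_long_edges(m, 4.0 / 3.0 * target);
      // repeated independent-set collapse sweeps until the mean approaches
      // the target (each sweep only collapses a 2-ring-disjoint edge set)
      for (int sweep = 0; sweep < 60; ++sweep) {
        if (m.mean_edge() >= 0.9 * target) break;
        if (collapse_short_edges(m, 0.8 * target, 4.0 / 3.0 * target) == 0)
          break;
      }
      collapse_short_edges(m, 0.8 * target, 4.0 / 3.0 * target);
      flip_pass(m);
      smooth_project(m, grid, 0.6);
      smooth_project(m, grid, 0.6);
      me = m.mean_edge();
      converged = me >= 0.9 * target && me <= 1.1 * target;
      Rcpp::checkUserInterrupt();
    }
  }

  NumericMatrix Vout(m.V.size(), 3);
  for (int i = 0; i < (int)m.V.size(); ++i)
    for (int k = 0; k < 3; ++k) Vout(i, k) = m.V[i][k];
  IntegerMatrix Fout(m.F.size(), 3);
  for (int f = 0; f < (int)m.F.size(); ++f)
    for (int k = 0; k < 3; ++k) Fout(f, k) = m.F[f][k] + 1;
  return List::create(_["vertices"] = Vout, _["faces"] = Fout,
                      _["mean_edge"] = me, _["converged"] = converged,
                      _["iterations"] = used);
}
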