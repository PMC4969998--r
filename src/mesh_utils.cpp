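#include <Rcpp.h>
#include <vector>
#include <queue>
#include <map>
#include <cstdint>
#include <functional>
using namespace Rcpp;

// Which faces must be flipped so that every shared edge is traversed in
// opposite directions by its two faces. BFS flood fill over face adjacency;
// each connected component keeps its seed face's winding.
// [[Rcpp::export]]
LogicalVector cpp_orient_faces(IntegerMatrix faces, int nverts) {
  int nf = faces.nrow();
  // undirected edge key -> incident faces (at most 2 used)
  std::map<uint64_t, std::vector<int>> edge_faces;
  auto key = [nverts](int a, int b) {
    int lo = a < b ? a : b, hi = a < b ? b : a;
    return (uint64_t)lo * (uint64_t)(nverts + 1) + (uint64_t)hi;
  };
  for (int f = 0; f < nf; ++f) {
    int v[3] = {faces(f, 0), faces(f, 1), faces(f, 2)};
    for (int e = 0; e < 3; ++e)
      edge_faces[key(v[e], v[(e + 1) % 3])].push_back(f);
  }
  std::vector<char> visited(nf, 0), flip(nf, 0);
  std::queue<int> q;
  for (int seed = 0; seed < nf; ++seed) {
    if (visited[seed]) continue;
    visited[seed] = 1;
    q.push(seed);
    while (!q.empty()) {
      int f = q.front(); q.pop();
      int v[3] = {faces(f, 0), faces(f, 1), faces(f, 2)};
      if (flip[f]) std::swap(v[1], v[2]);
      for (int e = 0; e < 3; ++e) {
        int a = v[e], b = v[(e + 1) % 3];
        const std::vector<int> &fl = edge_faces[key(a, b)];
        for (int g : fl) {
          if (g == f || visited[g]) continue;
          int w[3] = {faces(g, 0), faces(g, 1), faces(g, 2)};
          // g traverses edge in same direction a->b? then it must flip
          bool same = false;
          for (int e2 = 0; e2 < 3; ++e2)
            if (w[e2] == a && w[(e2 + 1) % 3] == b) same = true;
          flip[g] = same ? 1 : 0;
          visited[g] = 1;
          q.push(g);
        }
      }
    }
  }
  LogicalVector out(nf);
  for (int f = 0; f < nf; ++f) out[f] = flip[f] != 0;
  return out;
}

// Connected components of the vertex graph (union-find). 1-based labels.
// [[Rcpp::export]]
IntegerVector cpp_components(IntegerVector v1, IntegerVector v2, int nverts) {
  std::vector<int> parent(nverts + 1);
  for (int i = 0; i <= nverts; ++i) parent[i] = i;
  std::function<int(int)> find = [&](int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  };
  int ne = v1.size();
  for (int i = 0; i < ne; ++i) {
    int a = find(v1[i]), b = find(v2[i]);
    if (a != b) parent[b] = a;
  }
  IntegerVector out(nverts);
  for (int i = 1; i <= nverts; ++i) out[i - 1] = find(i);
  return out;
}
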