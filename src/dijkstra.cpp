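#include <Rcpp.h>
#include <vector>
#include <queue>
#include <limits>
using namespace Rcpp;

// Dijkstra on the mesh edge graph. Deterministic tie-break: among frontier
// entries of equal distance the lowest vertex index is settled first, and a
// vertex's parent is its first minimal predecessor (equal-cost relaxations
// never replace an earlier parent). `target` = 0 runs to exhaustion
// (full distance field); otherwise the search stops as soon as the target is
// settled. All indices 1-based.
// [[Rcpp::export]]
List cpp_dijkstra(int nverts, IntegerVector ev1, IntegerVector ev2,
                  NumericVector w, IntegerVector sources, int target) {
  const double INF = std::numeric_limits<double>::infinity();
  int ne = ev1.size();
  // CSR adjacency
  std::vector<int> deg(nverts + 1, 0);
  for (int i = 0; i < ne; ++i) { deg[ev1[i]]++; deg[ev2[i]]++; }
  std::vector<int> off(nverts + 2, 0);
  for (int v = 1; v <= nverts; ++v) off[v + 1] = off[v] + deg[v];
  std::vector<int> adj(2 * ne);
  std::vector<double> wt(2 * ne);
  std::vector<int> cur(nverts + 1, 0);
  for (int i = 0; i < ne; ++i) {
    int a = ev1[i], b = ev2[i];
    adj[off[a] + cur[a]] = b; wt[off[a] + cur[a]] = w[i]; cur[a]++;
    adj[off[b] + cur[b]] = a; wt[off[b] + cur[b]] = w[i]; cur[b]++;
  }

  std::vector<double> dist(nverts + 1, INF);
  std::vector<int> parent(nverts + 1, 0);
  std::vector<char> settled(nverts + 1, 0);
  typedef std::pair<double, int> QE;  // (dist, vertex): ties -> lowest index
  std::priority_queue<QE, std::vector<QE>, std::greater<QE>> pq;
  for (int i = 0; i < sources.size(); ++i) {
    int s = sources[i];
    dist[s] = 0.0;
    pq.push(QE(0.0, s));
  }
  while (!pq.empty()) {
    QE top = pq.top(); pq.pop();
    int u = top.second;
    if (settled[u]) continue;
    settled[u] = 1;
    if (u == target) break;
    double du = top.first;
    for (int k = off[u]; k < off[u + 1]; ++k) {
      int v = adj[k];
      if (settled[v]) continue;
      double nd = du + wt[k];
      if (nd < dist[v]) {  // strict: first minimal predecessor kept on ties
        dist[v] = nd;
        parent[v] = u;
        pq.push(QE(nd, v));
      }
    }
  }
  NumericVector dout(nverts);
  IntegerVector pout(nverts);
  for (int v = 1; v <= nverts; ++v) {
    dout[v - 1] = dist[v];
    pout[v - 1] = parent[v];
  }
  return List::create(_["dist"] = dout, _["parent"] = pout);
}
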