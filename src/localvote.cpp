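#include <Rcpp.h>
#include <vector>
#include <queue>
#include <utility>
using namespace Rcpp;

typedef std::pair<double, int> QN;  // (distance, face)

// Area-weighted majority vote over geodesic face neighborhoods.
// The face-adjacency graph (edges between faces sharing a mesh edge,
// weighted by centroid-to-centroid distance) approximates geodesic
// distances between faces; for each face a Dijkstra search truncated at
// `radius` collects the neighborhood and the label with the largest summed
// triangle area wins. Ties keep the incumbent label. Labels <= 0 (excluded)
// neither vote nor change.

// [[Rcpp::export(name = ".local_majority")]]
IntegerVector local_majority(IntegerVector labels, NumericVector areas,
                             IntegerMatrix adj, NumericVector w,
                             double radius, int iterations, int n_labels) {
  const int nf = labels.size(), ne = adj.nrow();
  // adjacency lists
  std::vector<std::vector<std::pair<int, double> > > nb(nf);
  for (int e = 0; e < ne; ++e) {
    int a = adj(e, 0) - 1, b = adj(e, 1) - 1;
    nb[a].push_back(std::make_pair(b, w[e]));
    nb[b].push_back(std::make_pair(a, w[e]));
  }
  std::vector<int> cur(labels.begin(), labels.end());
  std::vector<double> dist(nf, -1.0);
  std::vector<int> touched;
  std::vector<double> votes(n_labels + 1, 0.0);

  for (int it = 0; it < iterations; ++it) {
    std::vector<int> nxt(cur);
    for (int s = 0; s < nf; ++s) {
      if (cur[s] <= 0) continue;
      std::priority_queue<QN, std::vector<QN>, std::greater<QN> > pq;
      pq.push(std::make_pair(0.0, s));
      dist[s] = 0.0;
      touched.clear();
      touched.push_back(s);
      std::fill(votes.begin(), votes.end(), 0.0);
      while (!pq.empty()) {
        QN top = pq.top(); pq.pop();
        double d = top.first; int u = top.second;
        if (d > dist[u] + 1e-12) continue;
        if (cur[u] > 0) votes[cur[u]] += areas[u];
        for (std::size_t k = 0; k < nb[u].size(); ++k) {
          int v = nb[u][k].first;
          double nd = d + nb[u][k].second;
          if (nd > radius) continue;
          if (dist[v] < 0 || nd < dist[v]) {
            if (dist[v] < 0) touched.push_back(v);
            dist[v] = nd;
            pq.push(std::make_pair(nd, v));
          }
        }
      }
      int best = cur[s];
      double bestv = votes[cur[s]];
      for (int l = 1; l <= n_labels; ++l)
        if (votes[l] > bestv + 1e-12) { best = l; bestv = votes[l]; }
      nxt[s] = best;
      for (std::size_t k = 0; k < touched.size(); ++k)
        dist[touched[k]] = -1.0;
    }
    cur.swap(nxt);
  }
  return IntegerVector(cur.begin(), cur.end());
}

// Faces whose graph-geodesic centroid distance from `face` is <= radius.
// [[Rcpp::export(name = ".faces_within_radius")]]
IntegerVector faces_within_radius(int face, int nf, IntegerMatrix adj,
                                  NumericVector w, double radius) {
  std::vector<std::vector<std::pair<int, double> > > nb(nf);
  for (int e = 0; e < adj.nrow(); ++e) {
    int a = adj(e, 0) - 1, b = adj(e, 1) - 1;
    nb[a].push_back(std::make_pair(b, w[e]));
    nb[b].push_back(std::make_pair(a, w[e]));
  }
  std::vector<double> dist(nf, -1.0);
  std::priority_queue<QN, std::vector<QN>, std::greater<QN> > pq;
  int s = face - 1;
  pq.push(std::make_pair(0.0, s));
  dist[s] = 0.0;
  std::vector<int> out;
  while (!pq.empty()) {
    QN top = pq.top(); pq.pop();
    double d = top.first; int u = top.second;
    if (d > dist[u] + 1e-12) continue;
    out.push_back(u + 1);
    for (std::size_t k = 0; k < nb[u].size(); ++k) {
      int v = nb[u][k].first;
      double nd = d + nb[u][k].second;
      if (nd > radius) continue;
      if (dist[v] < 0 || nd < dist[v]) {
        dist[v] = nd;
        pq.push(std::make_pair(nd, v));
      }
    }
  }
  std::sort(out.begin(), out.end());
  return IntegerVector(out.begin(), out.end());
}
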