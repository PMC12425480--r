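#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Batched Moller-Trumbore ray casting against one triangle soup.
// For each ray i the nearest |t| > eps intersection along +dir and along
// -dir is found, skipping the per-ray excluded faces (local patch).
// Returns the minimum of the two directional distances (+Inf if no hit)
// plus the hit face (1-based, NA if none).

// [[Rcpp::export(name = ".trace_rays")]]
List trace_rays(NumericMatrix origins, NumericMatrix dirs,
                NumericMatrix V, IntegerMatrix F,
                List exclude, double eps) {
  const int nr = origins.nrow(), nf = F.nrow();
  NumericVector dist(nr);
  IntegerVector hit(nr);
  std::vector<char> excl(nf, 0);

  // precompute triangle vertices
  std::vector<double> ax(nf), ay(nf), az(nf), e1x(nf), e1y(nf), e1z(nf),
      e2x(nf), e2y(nf), e2z(nf);
  for (int f = 0; f < nf; ++f) {
    int i0 = F(f, 0) - 1, i1 = F(f, 1) - 1, i2 = F(f, 2) - 1;
    ax[f] = V(i0, 0); ay[f] = V(i0, 1); az[f] = V(i0, 2);
    e1x[f] = V(i1, 0) - ax[f]; e1y[f] = V(i1, 1) - ay[f];
    e1z[f] = V(i1, 2) - az[f];
    e2x[f] = V(i2, 0) - ax[f]; e2y[f] = V(i2, 1) - ay[f];
    e2z[f] = V(i2, 2) - az[f];
  }

  for (int r = 0; r < nr; ++r) {
    IntegerVector ex = exclude[r];
    for (int k = 0; k < ex.size(); ++k) excl[ex[k] - 1] = 1;
    double ox = origins(r, 0), oy = origins(r, 1), oz = origins(r, 2);
    double dx = dirs(r, 0), dy = dirs(r, 1), dz = dirs(r, 2);
    double best = R_PosInf; int bestf = NA_INTEGER;
    for (int f = 0; f < nf; ++f) {
      if (excl[f]) continue;
      // p = d x e2
      double px = dy * e2z[f] - dz * e2y[f];
      double py = dz * e2x[f] - dx * e2z[f];
      double pz = dx * e2y[f] - dy * e2x[f];
      double det = e1x[f] * px + e1y[f] * py + e1z[f] * pz;
      if (std::fabs(det) < 1e-12) continue;
      double inv = 1.0 / det;
      double tx = ox - ax[f], ty = oy - ay[f], tz = oz - az[f];
      double u = (tx * px + ty * py + tz * pz) * inv;
      if (u < -1e-9 || u > 1 + 1e-9) continue;
      double qx = ty * e1z[f] - tz * e1y[f];
      double qy = tz * e1x[f] - tx * e1z[f];
      double qz = tx * e1y[f] - ty * e1x[f];
      double v = (dx * qx + dy * qy + dz * qz) * inv;
      if (v < -1e-9 || u + v > 1 + 1e-9) continue;
      double t = (e2x[f] * qx + e2y[f] * qy + e2z[f] * qz) * inv;
      double at = std::fabs(t);
      if (at > eps && at < best) { best = at; bestf = f + 1; }
    }
    dist[r] = best;
    hit[r] = bestf;
    for (int k = 0; k < ex.size(); ++k) excl[ex[k] - 1] = 0;
  }
  return List::create(_["distance"] = dist, _["face"] = hit);
}
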