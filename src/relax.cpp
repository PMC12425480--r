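#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Coordinate-descent relaxation of a polyline whose interior nodes are
// constrained to mesh edges (support vertices sup_a -> sup_b). Each sweep
// minimizes, per node, |A - P(t)| + |P(t) - B| over t in [0,1] by golden
// section (the objective is convex in t). Nodes with sup_a == sup_b or
// sup == 0 are fixed. Returns the final length and node positions.

// [[Rcpp::export(name = ".relax_chain_cpp")]]
List relax_chain_cpp(NumericMatrix P_, IntegerVector sup_a,
                     IntegerVector sup_b, NumericMatrix verts,
                     int max_sweeps, double tol) {
  NumericMatrix P(clone(P_));
  const int n = P.nrow();
  auto seg = [&](int i) {
    double dx = P(i, 0) - P(i + 1, 0), dy = P(i, 1) - P(i + 1, 1),
           dz = P(i, 2) - P(i + 1, 2);
    return std::sqrt(dx * dx + dy * dy + dz * dz);
  };
  double total = 0;
  for (int i = 0; i < n - 1; ++i) total += seg(i);
  std::vector<int> mov;
  for (int i = 1; i < n - 1; ++i)
    if (sup_a[i] > 0 && sup_b[i] > 0 && sup_a[i] != sup_b[i])
      mov.push_back(i);
  if (mov.empty() || n == 2)
    return List::create(_["len"] = total, _["P"] = P);

  const double gr = (std::sqrt(5.0) - 1.0) / 2.0;
  for (int sweep = 0; sweep < max_sweeps; ++sweep) {
    double prev = total;
    for (std::size_t j = 0; j < mov.size(); ++j) {
      int i = mov[j];
      double e0x = verts(sup_a[i] - 1, 0), e0y = verts(sup_a[i] - 1, 1),
             e0z = verts(sup_a[i] - 1, 2);
      double dx = verts(sup_b[i] - 1, 0) - e0x,
             dy = verts(sup_b[i] - 1, 1) - e0y,
             dz = verts(sup_b[i] - 1, 2) - e0z;
      double ax = P(i - 1, 0), ay = P(i - 1, 1), az = P(i - 1, 2);
      double bx = P(i + 1, 0), by = P(i + 1, 1), bz = P(i + 1, 2);
      auto f = [&](double t) {
        double qx = e0x + t * dx, qy = e0y + t * dy, qz = e0z + t * dz;
        double d1 = std::sqrt((qx - ax) * (qx - ax) + (qy - ay) * (qy - ay) +
                              (qz - az) * (qz - az));
        double d2 = std::sqrt((qx - bx) * (qx - bx) + (qy - by) * (qy - by) +
                              (qz - bz) * (qz - bz));
        return d1 + d2;
      };
      double lo = 0.0, hi = 1.0;
      double c = hi - gr * (hi - lo), d = lo + gr * (hi - lo);
      double fc = f(c), fd = f(d);
      for (int it = 0; it < 60 && hi - lo > 1e-12; ++it) {
        if (fc < fd) {
          hi = d; d = c; fd = fc;
          c = hi - gr * (hi - lo); fc = f(c);
        } else {
          lo = c; c = d; fc = fd;
          d = lo + gr * (hi - lo); fd = f(d);
        }
      }
      double t = (fc < fd) ? c : d;
      if (f(0.0) <= f(t)) t = 0.0;
      if (f(1.0) < f(t)) t = 1.0;
      P(i, 0) = e0x + t * dx; P(i, 1) = e0y + t * dy; P(i, 2) = e0z + t * dz;
    }
    total = 0;
    for (int i = 0; i < n - 1; ++i) total += seg(i);
    if (prev - total < tol * std::max(1.0, total)) break;
  }
  return List::create(_["len"] = total, _["P"] = P);
}
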