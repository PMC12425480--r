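#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Isosurface extraction by marching tetrahedra: each grid cube is split into
// six tetrahedra (shared main diagonal, so faces agree between neighbors) and
// each tetrahedron contributes 0-2 triangles with vertices linearly
// interpolated onto the iso level. Triangles are oriented so that the normal
// points from values above the iso level (inside) to values below (outside).

static const int TET[6][4] = {
  {0, 5, 1, 6}, {0, 1, 2, 6}, {0, 2, 3, 6},
  {0, 3, 7, 6}, {0, 7, 4, 6}, {0, 4, 5, 6}
};
// cube corner offsets (x, y, z)
static const int CRN[8][3] = {
  {0, 0, 0}, {1, 0, 0}, {1, 1, 0}, {0, 1, 0},
  {0, 0, 1}, {1, 0, 1}, {1, 1, 1}, {0, 1, 1}
};

struct Key {
  std::uint64_t a, b;
  bool operator==(const Key& o) const { return a == o.a && b == o.b; }
};
struct KeyHash {
  std::size_t operator()(const Key& k) const {
    return std::hash<std::uint64_t>()(k.a * 1000003ULL ^ k.b);
  }
};

// [[Rcpp::export(name = ".march_tets")]]
List march_tets(NumericVector vol, IntegerVector dims, double iso) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  auto V = [&](int x, int y, int z) -> double {
    return vol[(std::size_t)x + (std::size_t)nx * (y + (std::size_t)ny * z)];
  };
  auto nid = [&](int x, int y, int z) -> std::uint64_t {
    return (std::uint64_t)x + (std::uint64_t)nx * (y + (std::uint64_t)ny * z);
  };

  std::unordered_map<Key, int, KeyHash> vmap;
  std::vector<double> verts;   // interleaved xyz (voxel units, 0-based)
  std::vector<int> tris;       // interleaved 1-based vertex ids

  auto edge_vertex = [&](std::uint64_t n1, double v1, double px1, double py1,
                         double pz1, std::uint64_t n2, double v2, double px2,
                         double py2, double pz2) -> int {
    Key k;
    if (n1 < n2) { k.a = n1; k.b = n2; } else { k.a = n2; k.b = n1; }
    auto it = vmap.find(k);
    if (it != vmap.end()) return it->second;
    double t = (iso - v1) / (v2 - v1);
    if (t < 0) t = 0; if (t > 1) t = 1;
    verts.push_back(px1 + t * (px2 - px1));
    verts.push_back(py1 + t * (py2 - py1));
    verts.push_back(pz1 + t * (pz2 - pz1));
    int id = (int)(verts.size() / 3);  // 1-based
    vmap.emplace(k, id);
    return id;
  };

  double cv[8]; std::uint64_t cn[8]; double cx[8], cy[8], cz[8];
  for (int z = 0; z + 1 < nz; ++z)
    for (int y = 0; y + 1 < ny; ++y)
      for (int x = 0; x + 1 < nx; ++x) {
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) {
          int xx = x + CRN[c][0], yy = y + CRN[c][1], zz = z + CRN[c][2];
          cv[c] = V(xx, yy, zz);
          cn[c] = nid(xx, yy, zz);
          cx[c] = xx; cy[c] = yy; cz[c] = zz;
          if (cv[c] > iso) any_in = true; else any_out = true;
        }
        if (!any_in || !any_out) continue;
        for (int t = 0; t < 6; ++t) {
          int a = TET[t][0], b = TET[t][1], c = TET[t][2], d = TET[t][3];
          int ids[4] = {a, b, c, d};
          // classify
          bool in[4];
          int n_in = 0;
          for (int i = 0; i < 4; ++i) {
            in[i] = cv[ids[i]] > iso;
            if (in[i]) ++n_in;
          }
          if (n_in == 0 || n_in == 4) continue;
          auto EV = [&](int i, int j) {
            int u = ids[i], w = ids[j];
            return edge_vertex(cn[u], cv[u], cx[u], cy[u], cz[u],
                               cn[w], cv[w], cx[w], cy[w], cz[w]);
          };
          // enumerate inside corners
          int ins[4], outs[4], ni = 0, no = 0;
          for (int i = 0; i < 4; ++i) (in[i] ? ins[ni++] : outs[no++]) = i;
          if (n_in == 1) {
            int p = ins[0];
            int e0 = EV(p, outs[0]), e1 = EV(p, outs[1]), e2 = EV(p, outs[2]);
            tris.push_back(e0); tris.push_back(e1); tris.push_back(e2);
          } else if (n_in == 3) {
            int p = outs[0];
            int e0 = EV(ins[0], p), e1 = EV(ins[1], p), e2 = EV(ins[2], p);
            tris.push_back(e0); tris.push_back(e1); tris.push_back(e2);
          } else {  // 2 in, 2 out -> quad, split into two triangles
            int e00 = EV(ins[0], outs[0]), e01 = EV(ins[0], outs[1]);
            int e10 = EV(ins[1], outs[0]), e11 = EV(ins[1], outs[1]);
            tris.push_back(e00); tris.push_back(e01); tris.push_back(e11);
            tris.push_back(e00); tris.push_back(e11); tris.push_back(e10);
          }
        }
      }

  int nv = (int)(verts.size() / 3), nt = (int)(tris.size() / 3);
  NumericMatrix Vm(nv, 3);
  for (int i = 0; i < nv; ++i)
    for (int j = 0; j < 3; ++j) Vm(i, j) = verts[3 * i + j];
  IntegerMatrix Fm(nt, 3);
  for (int i = 0; i < nt; ++i)
    for (int j = 0; j < 3; ++j) Fm(i, j) = tris[3 * i + j];

  // orient triangles: normal should point toward decreasing field value
  auto sampleV = [&](double px, double py, double pz) -> double {
    int ix = (int)px, iy = (int)py, iz = (int)pz;
    if (ix > nx - 2) ix = nx - 2; if (iy > ny - 2) iy = ny - 2;
    if (iz > nz - 2) iz = nz - 2;
    double fx = px - ix, fy = py - iy, fz = pz - iz;
    double s = 0;
    for (int dx = 0; dx < 2; ++dx)
      for (int dy = 0; dy < 2; ++dy)
        for (int dz = 0; dz < 2; ++dz)
          s += V(ix + dx, iy + dy, iz + dz) *
               (dx ? fx : 1 - fx) * (dy ? fy : 1 - fy) * (dz ? fz : 1 - fz);
    return s;
  };
  const double h = 0.25;
  for (int i = 0; i < nt; ++i) {
    int a = Fm(i, 0) - 1, b = Fm(i, 1) - 1, c = Fm(i, 2) - 1;
    double e1x = Vm(b, 0) - Vm(a, 0), e1y = Vm(b, 1) - Vm(a, 1),
           e1z = Vm(b, 2) - Vm(a, 2);
    double e2x = Vm(c, 0) - Vm(a, 0), e2y = Vm(c, 1) - Vm(a, 1),
           e2z = Vm(c, 2) - Vm(a, 2);
    double ncx = e1y * e2z - e1z * e2y, ncy = e1z * e2x - e1x * e2z,
           ncz = e1x * e2y - e1y * e2x;
    double nn = std::sqrt(ncx * ncx + ncy * ncy + ncz * ncz);
    if (nn <= 0) continue;
    double gx = (Vm(a, 0) + Vm(b, 0) + Vm(c, 0)) / 3.0;
    double gy = (Vm(a, 1) + Vm(b, 1) + Vm(c, 1)) / 3.0;
    double gz = (Vm(a, 2) + Vm(b, 2) + Vm(c, 2)) / 3.0;
    double px = gx + h * ncx / nn, py = gy + h * ncy / nn,
           pz = gz + h * ncz / nn;
    double mx = gx - h * ncx / nn, my = gy - h * ncy / nn,
           mz = gz - h * ncz / nn;
    if (px < 0 || py < 0 || pz < 0 || px > nx - 1 || py > ny - 1 ||
        pz > nz - 1 || mx < 0 || my < 0 || mz < 0 || mx > nx - 1 ||
        my > ny - 1 || mz > nz - 1)
      continue;
    if (sampleV(px, py, pz) > sampleV(mx, my, mz)) {
      int tmp = Fm(i, 1); Fm(i, 1) = Fm(i, 2); Fm(i, 2) = tmp;
    }
  }
  return List::create(_["vertices"] = Vm, _["faces"] = Fm);
}
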