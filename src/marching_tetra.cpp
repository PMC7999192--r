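#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Iso-surface extraction by marching tetrahedra on the Kuhn (6-tet)
// subdivision of each grid cell. The Kuhn subdivision is translation
// consistent (opposite cube faces carry parallel diagonals), so adjacent
// cells triangulate shared faces identically and the result is watertight
// on any field whose iso-surface stays clear of the volume border.
//
// Vertices are emitted in continuous 0-based voxel-index coordinates;
// conversion to world millimetres happens on the R side.

struct V3 { double x, y, z; };

static inline uint64_t edge_key(uint64_t a, uint64_t b) {
  if (a > b) std::swap(a, b);
  return (a << 32) | b;
}

//' @noRd
// [[Rcpp::export(name = ".marching_tetrahedra")]]
List marching_tetrahedra(NumericVector field, IntegerVector dims, double level) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (field.size() != n) stop("field length does not match dims");

  // cube corner offsets, bit encoding b = dx + 2*dy + 4*dz
  const int cdx[8] = {0,1,0,1,0,1,0,1};
  const int cdy[8] = {0,0,1,1,0,0,1,1};
  const int cdz[8] = {0,0,0,0,1,1,1,1};
  // Kuhn tetrahedra: monotone bit paths 0 -> 7
  const int tets[6][4] = {
    {0,1,3,7},{0,1,5,7},{0,2,3,7},{0,2,6,7},{0,4,5,7},{0,4,6,7}
  };

  std::unordered_map<uint64_t, int> vmap;
  std::vector<V3> verts;
  std::vector<int> faces; // triples of 0-based vertex indices
  const double* F = REAL(field);

  double gx[8], gy[8], gz[8], fv[8];
  uint64_t gid[8];

  for (int z = 0; z < nz - 1; ++z)
    for (int y = 0; y < ny - 1; ++y)
      for (int x = 0; x < nx - 1; ++x) {
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) {
          int xx = x + cdx[c], yy = y + cdy[c], zz = z + cdz[c];
          uint64_t i = (uint64_t)xx + (uint64_t)nx * ((uint64_t)yy + (uint64_t)ny * zz);
          gid[c] = i; fv[c] = F[i];
          gx[c] = xx; gy[c] = yy; gz[c] = zz;
          if (fv[c] > level) any_in = true; else any_out = true;
        }
        if (!any_in || !any_out) continue;

        for (int t = 0; t < 6; ++t) {
          int in_idx[4], out_idx[4], ni = 0, no = 0;
          for (int k = 0; k < 4; ++k) {
            int c = tets[t][k];
            if (fv[c] > level) in_idx[ni++] = c; else out_idx[no++] = c;
          }
          if (ni == 0 || ni == 4) continue;

          // interpolated vertex on edge (a in, b out)
          auto ev = [&](int a, int b) -> int {
            uint64_t key = edge_key(gid[a], gid[b]);
            auto it = vmap.find(key);
            if (it != vmap.end()) return it->second;
            double d = fv[a] - fv[b];
            double s = (std::fabs(d) < 1e-300) ? 0.5 : (fv[a] - level) / d;
            V3 p;
            p.x = gx[a] + s * (gx[b] - gx[a]);
            p.y = gy[a] + s * (gy[b] - gy[a]);
            p.z = gz[a] + s * (gz[b] - gz[a]);
            int idx = (int)verts.size();
            verts.push_back(p);
            vmap[key] = idx;
            return idx;
          };

          // orient each triangle so its normal points to the outside (f <= level)
          auto emit = [&](int i0, int i1, int i2) {
            const V3 &p0 = verts[i0], &p1 = verts[i1], &p2 = verts[i2];
            double ux = p1.x - p0.x, uy = p1.y - p0.y, uz = p1.z - p0.z;
            double vx = p2.x - p0.x, vy = p2.y - p0.y, vz = p2.z - p0.z;
            double nxv = uy * vz - uz * vy;
            double nyv = uz * vx - ux * vz;
            double nzv = ux * vy - uy * vx;
            double cxi = 0, cyi = 0, czi = 0, cxo = 0, cyo = 0, czo = 0;
            for (int k = 0; k < ni; ++k) { cxi += gx[in_idx[k]]; cyi += gy[in_idx[k]]; czi += gz[in_idx[k]]; }
            for (int k = 0; k < no; ++k) { cxo += gx[out_idx[k]]; cyo += gy[out_idx[k]]; czo += gz[out_idx[k]]; }
            double dx = cxo / no - cxi / ni, dy = cyo / no - cyi / ni, dz = czo / no - czi / ni;
            if (nxv * dx + nyv * dy + nzv * dz < 0) std::swap(i1, i2);
            faces.push_back(i0); faces.push_back(i1); faces.push_back(i2);
          };

          if (ni == 1) {
            int a = in_idx[0];
            emit(ev(a, out_idx[0]), ev(a, out_idx[1]), ev(a, out_idx[2]));
          } else if (ni == 3) {
            int b = out_idx[0];
            emit(ev(in_idx[0], b), ev(in_idx[1], b), ev(in_idx[2], b));
          } else { // 2 in, 2 out -> quad
            int a0 = in_idx[0], a1 = in_idx[1], b0 = out_idx[0], b1 = out_idx[1];
            int q0 = ev(a0, b0), q1 = ev(a0, b1), q2 = ev(a1, b1), q3 = ev(a1, b0);
            emit(q0, q1, q2);
            emit(q0, q2, q3);
          }
        }
      }

  NumericMatrix Vm(verts.size(), 3);
  for (size_t i = 0; i < verts.size(); ++i) {
    Vm(i, 0) = verts[i].x; Vm(i, 1) = verts[i].y; Vm(i, 2) = verts[i].z;
  }
  IntegerMatrix Fm(faces.size() / 3, 3);
  for (size_t i = 0; i < faces.size() / 3; ++i) {
    Fm(i, 0) = faces[3 * i] + 1; Fm(i, 1) = faces[3 * i + 1] + 1; Fm(i, 2) = faces[3 * i + 2] + 1;
  }
  return List::create(_["vertices"] = Vm, _["faces"] = Fm);
}
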