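#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Union-find with path halving.
static inline int uf_find(std::vector<int>& parent, int x) {
  while (parent[x] != x) {
    parent[x] = parent[parent[x]];
    x = parent[x];
  }
  return x;
}

static inline void uf_union(std::vector<int>& parent, int a, int b) {
  int ra = uf_find(parent, a), rb = uf_find(parent, b);
  if (ra != rb) parent[std::max(ra, rb)] = std::min(ra, rb);
}

//' @noRd
// [[Rcpp::export(name = ".cc_label26")]]
IntegerVector cc_label26(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dims");

  std::vector<int> parent(n);
  for (R_xlen_t i = 0; i < n; ++i) parent[i] = (int)i;

  // 13 previously-scanned neighbours in column-major order (dx + nx*dy + nx*ny*dz < 0)
  int offs[13][3]; int no = 0;
  for (int dz = -1; dz <= 0; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dz == 0 && (dy > 0 || (dy == 0 && dx >= 0))) continue;
        offs[no][0] = dx; offs[no][1] = dy; offs[no][2] = dz; ++no;
      }

  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        R_xlen_t i = x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
        if (!mask[i]) continue;
        for (int k = 0; k < no; ++k) {
          int xx = x + offs[k][0], yy = y + offs[k][1], zz = z + offs[k][2];
          if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny) continue;
          R_xlen_t j = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
          if (mask[j]) uf_union(parent, (int)i, (int)j);
        }
      }

  IntegerVector out(n);
  std::vector<int> relabel(n, 0);
  int next = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i]) { out[i] = 0; continue; }
    int r = uf_find(parent, (int)i);
    if (relabel[r] == 0) relabel[r] = ++next;
    out[i] = relabel[r];
  }
  out.attr("n_components") = next;
  return out;
}
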