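#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Union-find connected-component labeling on a 2D or 3D logical grid.
// Connectivity is "full" neighborhood: 8-connectivity in 2D, 26 in 3D.
// Returns an integer grid with components labeled 1..K in first-voxel order.

static int uf_find(std::vector<int> &parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

static void uf_union(std::vector<int> &parent, int a, int b) {
  int ra = uf_find(parent, a), rb = uf_find(parent, b);
  if (ra != rb) parent[ra < rb ? rb : ra] = (ra < rb ? ra : rb);
}

// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dim) {
  const int ndim = dim.size();
  const int nz = dim[0];
  const int ny = ndim >= 2 ? dim[1] : 1;
  const int nx = ndim >= 3 ? dim[2] : 1;
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;

  std::vector<int> parent(n);
  const int *M = mask.begin();

  // pass 1: link each foreground voxel to lexicographically earlier neighbors
  for (int x = 0; x < nx; ++x) {
    for (int y = 0; y < ny; ++y) {
      for (int z = 0; z < nz; ++z) {
        const R_xlen_t i = z + (R_xlen_t)nz * (y + (R_xlen_t)ny * x);
        parent[i] = (int)i;
        if (!M[i]) continue;
        for (int dx = -1; dx <= 0; ++dx) {
          const int xx = x + dx;
          if (xx < 0) continue;
          for (int dy = -1; dy <= 1; ++dy) {
            const int yy = y + dy;
            if (yy < 0 || yy >= ny) continue;
            for (int dz = -1; dz <= 1; ++dz) {
              const int zz = z + dz;
              if (zz < 0 || zz >= nz) continue;
              // only neighbors strictly earlier in (x, y, z) order
              if (dx == 0 && (dy > 0 || (dy == 0 && dz >= 0))) continue;
              const R_xlen_t j = zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx);
              if (M[j]) uf_union(parent, (int)i, (int)j);
            }
          }
        }
      }
    }
  }

  // pass 2: compress and assign compact labels in root order of appearance
  IntegerVector out(n);
  std::vector<int> label(n, 0);
  int next = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!M[i]) { out[i] = 0; continue; }
    const int r = uf_find(parent, (int)i);
    if (label[r] == 0) label[r] = ++next;
    out[i] = label[r];
  }
  out.attr("dim") = dim;
  return out;
}
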