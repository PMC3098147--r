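#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Exact squared Euclidean distance transform (Felzenszwalb & Huttenlocher's
// separable lower-envelope algorithm) on a 2D or 3D grid, in voxel units.
// Distance is to the nearest TRUE element of the mask.

static const double INF = std::numeric_limits<double>::infinity();

static void dt1d(const double *f, double *d, int *v, double *z, int n) {
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    if (f[q] == INF) continue;
    if (k == 0 && f[v[0]] == INF) { v[0] = q; continue; }
    double s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (k > 0 && s <= z[k]) {
      --k;
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    if (f[v[0]] == INF) { d[q] = INF; continue; }
    while (z[k + 1] < q) ++k;
    const double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// dt1d with nearest-site propagation: s_in[q] holds the linear index of the
// nearest TRUE voxel feeding f[q]; s_out receives the winner per position
static void dt1d_sites(const double *f, double *d, int *v, double *z, int n,
                       const int *s_in, int *s_out) {
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    if (f[q] == INF) continue;
    if (k == 0 && f[v[0]] == INF) { v[0] = q; continue; }
    double s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (k > 0 && s <= z[k]) {
      --k;
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    if (f[v[0]] == INF) { d[q] = INF; s_out[q] = -1; continue; }
    while (z[k + 1] < q) ++k;
    const double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
    s_out[q] = s_in[v[k]];
  }
}

// Squared EDT that also reports, per voxel, the linear (0-based) index of
// the nearest TRUE voxel. Used to evaluate distances at off-grid points.
// [[Rcpp::export]]
List cpp_sqedt_sites(LogicalVector mask, IntegerVector dim) {
  const int ndim = dim.size();
  const int nz = dim[0];
  const int ny = ndim >= 2 ? dim[1] : 1;
  const int nx = ndim >= 3 ? dim[2] : 1;
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;

  NumericVector dist(n);
  IntegerVector site(n);
  double *D = dist.begin();
  int *S = site.begin();
  const int *M = mask.begin();
  for (R_xlen_t i = 0; i < n; ++i) {
    D[i] = M[i] ? 0.0 : INF;
    S[i] = M[i] ? (int)i : -1;
  }

  const int nmax = std::max(nz, std::max(ny, nx));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax), sin_(nmax), sout(nmax);

  // along z
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      const R_xlen_t base = (R_xlen_t)nz * (y + (R_xlen_t)ny * x);
      for (int q = 0; q < nz; ++q) { f[q] = D[base + q]; sin_[q] = S[base + q]; }
      dt1d_sites(f.data(), d.data(), v.data(), z.data(), nz,
                 sin_.data(), sout.data());
      for (int q = 0; q < nz; ++q) { D[base + q] = d[q]; S[base + q] = sout[q]; }
    }

  // along y
  for (int x = 0; x < nx; ++x)
    for (int z_ = 0; z_ < nz; ++z_) {
      for (int q = 0; q < ny; ++q) {
        const R_xlen_t i = z_ + (R_xlen_t)nz * (q + (R_xlen_t)ny * x);
        f[q] = D[i]; sin_[q] = S[i];
      }
      dt1d_sites(f.data(), d.data(), v.data(), z.data(), ny,
                 sin_.data(), sout.data());
      for (int q = 0; q < ny; ++q) {
        const R_xlen_t i = z_ + (R_xlen_t)nz * (q + (R_xlen_t)ny * x);
        D[i] = d[q]; S[i] = sout[q];
      }
    }

  // along x
  if (nx > 1)
    for (int y = 0; y < ny; ++y)
      for (int z_ = 0; z_ < nz; ++z_) {
        for (int q = 0; q < nx; ++q) {
          const R_xlen_t i = z_ + (R_xlen_t)nz * (y + (R_xlen_t)ny * q);
          f[q] = D[i]; sin_[q] = S[i];
        }
        dt1d_sites(f.data(), d.data(), v.data(), z.data(), nx,
                   sin_.data(), sout.data());
        for (int q = 0; q < nx; ++q) {
          const R_xlen_t i = z_ + (R_xlen_t)nz * (y + (R_xlen_t)ny * q);
          D[i] = d[q]; S[i] = sout[q];
        }
      }

  return List::create(Named("dist2") = dist, Named("site") = site);
}

// [[Rcpp::export]]
NumericVector cpp_sqedt(LogicalVector mask, IntegerVector dim) {
  const int ndim = dim.size();
  const int nz = dim[0];
  const int ny = ndim >= 2 ? dim[1] : 1;
  const int nx = ndim >= 3 ? dim[2] : 1;
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;

  NumericVector out(n);
  double *D = out.begin();
  const int *M = mask.begin();
  for (R_xlen_t i = 0; i < n; ++i) D[i] = M[i] ? 0.0 : INF;

  const int nmax = std::max(nz, std::max(ny, nx));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // along z
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      double *col = D + (R_xlen_t)nz * (y + (R_xlen_t)ny * x);
      for (int z_ = 0; z_ < nz; ++z_) f[z_] = col[z_];
      dt1d(f.data(), d.data(), v.data(), z.data(), nz);
      for (int z_ = 0; z_ < nz; ++z_) col[z_] = d[z_];
    }

  // along y
  for (int x = 0; x < nx; ++x)
    for (int z_ = 0; z_ < nz; ++z_) {
      for (int y = 0; y < ny; ++y)
        f[y] = D[z_ + (R_xlen_t)nz * (y + (R_xlen_t)ny * x)];
      dt1d(f.data(), d.data(), v.data(), z.data(), ny);
      for (int y = 0; y < ny; ++y)
        D[z_ + (R_xlen_t)nz * (y + (R_xlen_t)ny * x)] = d[y];
    }

  // along x
  if (nx > 1)
    for (int y = 0; y < ny; ++y)
      for (int z_ = 0; z_ < nz; ++z_) {
        for (int x = 0; x < nx; ++x)
          f[x] = D[z_ + (R_xlen_t)nz * (y + (R_xlen_t)ny * x)];
        dt1d(f.data(), d.data(), v.data(), z.data(), nx);
        for (int x = 0; x < nx; ++x)
          D[z_ + (R_xlen_t)nz * (y + (R_xlen_t)ny * x)] = d[x];
      }

  out.attr("dim") = dim;
  return out;
}
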