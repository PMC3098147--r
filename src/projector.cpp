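#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Parallel-beam forward projector, rotation axis = z (first array dimension).
// vol is a (nz, ny, nx) array in column-major order; angles are in radians,
// 0 rad rays travel along +x and the detector coordinate then equals y.
// Samples are taken at unit (voxel) steps along each ray with bilinear
// interpolation in the (y, x) plane; voxels outside the grid contribute 0.
// Returns the raw ray sums (caller multiplies by the voxel pitch to obtain
// line integrals); output dim (nz, ndet, n_angles) with ndet = ny.
// [[Rcpp::export]]
NumericVector cpp_project(NumericVector vol, IntegerVector dim,
                          NumericVector angles) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const int nA = angles.size();
  const int ndet = ny;
  const double cy = (ny - 1) / 2.0, cx = (nx - 1) / 2.0;
  const double cdet = (ndet - 1) / 2.0;
  const int ns = (int)std::ceil(std::sqrt((double)nx * nx + (double)ny * ny)) + 2;
  const double cs = (ns - 1) / 2.0;

  NumericVector out((R_xlen_t)nz * ndet * nA);
  const double *V = vol.begin();
  double *O = out.begin();

  for (int a = 0; a < nA; ++a) {
    const double ct = std::cos(angles[a]), st = std::sin(angles[a]);
    for (int j = 0; j < ndet; ++j) {
      const double t = j - cdet;
      double *ocol = O + (R_xlen_t)nz * (j + (R_xlen_t)ndet * a);
      for (int s = 0; s < ns; ++s) {
        const double sp = s - cs;
        // position = center + t * u + sp * d, with d = (ct, st), u = (-st, ct)
        const double x = cx - t * st + sp * ct;
        const double y = cy + t * ct + sp * st;
        const int x0 = (int)std::floor(x), y0 = (int)std::floor(y);
        if (x0 < -1 || x0 > nx - 1 || y0 < -1 || y0 > ny - 1) continue;
        const double fx = x - x0, fy = y - y0;
        const bool okx0 = x0 >= 0, okx1 = x0 + 1 <= nx - 1;
        const bool oky0 = y0 >= 0, oky1 = y0 + 1 <= ny - 1;
        const double w00 = (oky0 && okx0) ? (1 - fy) * (1 - fx) : 0.0;
        const double w10 = (oky1 && okx0) ? fy * (1 - fx) : 0.0;
        const double w01 = (oky0 && okx1) ? (1 - fy) * fx : 0.0;
        const double w11 = (oky1 && okx1) ? fy * fx : 0.0;
        if (w00 == 0.0 && w10 == 0.0 && w01 == 0.0 && w11 == 0.0) continue;
        const R_xlen_t b00 = (R_xlen_t)nz * ((oky0 ? y0 : 0) + (R_xlen_t)ny * (okx0 ? x0 : 0));
        const R_xlen_t b10 = (R_xlen_t)nz * ((oky1 ? y0 + 1 : 0) + (R_xlen_t)ny * (okx0 ? x0 : 0));
        const R_xlen_t b01 = (R_xlen_t)nz * ((oky0 ? y0 : 0) + (R_xlen_t)ny * (okx1 ? x0 + 1 : 0));
        const R_xlen_t b11 = (R_xlen_t)nz * ((oky1 ? y0 + 1 : 0) + (R_xlen_t)ny * (okx1 ? x0 + 1 : 0));
        for (int z = 0; z < nz; ++z) {
          ocol[z] += w00 * V[b00 + z] + w10 * V[b10 + z] +
                     w01 * V[b01 + z] + w11 * V[b11 + z];
        }
      }
    }
  }
  return out;
}

// Back-projection of (already filtered) sinograms.
// sino dim (nz, nA, ndet); returns (nz, ndet, ndet). Linear interpolation on
// the detector axis; angle weighting (d-theta) is applied by the caller.
// [[Rcpp::export]]
NumericVector cpp_backproject(NumericVector sino, IntegerVector dim,
                              NumericVector angles) {
  const int nz = dim[0], nA = dim[1], ndet = dim[2];
  const int ny = ndet, nx = ndet;
  const double cy = (ny - 1) / 2.0, cx = (nx - 1) / 2.0;
  const double cdet = (ndet - 1) / 2.0;

  NumericVector out((R_xlen_t)nz * ny * nx);
  const double *S = sino.begin();
  double *O = out.begin();

  for (int a = 0; a < nA; ++a) {
    const double ct = std::cos(angles[a]), st = std::sin(angles[a]);
    for (int x = 0; x < nx; ++x) {
      for (int y = 0; y < ny; ++y) {
        // detector coordinate of this pixel: t = u . (p - c), u = (-st, ct)
        const double t = -(x - cx) * st + (y - cy) * ct + cdet;
        const int t0 = (int)std::floor(t);
        if (t0 < -1 || t0 > ndet - 1) continue;
        const double ft = t - t0;
        const bool ok0 = t0 >= 0, ok1 = t0 + 1 <= ndet - 1;
        const double w0 = ok0 ? 1 - ft : 0.0;
        const double w1 = ok1 ? ft : 0.0;
        if (w0 == 0.0 && w1 == 0.0) continue;
        const R_xlen_t s0 = (R_xlen_t)nz * (a + (R_xlen_t)nA * (ok0 ? t0 : 0));
        const R_xlen_t s1 = (R_xlen_t)nz * (a + (R_xlen_t)nA * (ok1 ? t0 + 1 : 0));
        double *ocol = O + (R_xlen_t)nz * (y + (R_xlen_t)ny * x);
        for (int z = 0; z < nz; ++z) {
          ocol[z] += w0 * S[s0 + z] + w1 * S[s1 + z];
        }
      }
    }
  }
  return out;
}
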