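#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Felzenszwalb & Huttenlocher lower-envelope 1D squared distance transform,
// sampled at spacing w. Uses a large finite sentinel instead of infinity so
// the envelope arithmetic stays well defined for empty lines.
static const double CS_BIG = 1e15;

static void dt1d(std::vector<double> &f, std::vector<double> &d,
                 std::vector<int> &v, std::vector<double> &z, double w) {
  const int n = (int)f.size();
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  const double w2 = w * w;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      const int p = v[k];
      s = ((f[q] + w2 * q * q) - (f[p] + w2 * p * p)) / (2.0 * w2 * (q - p));
      if (s <= z[k]) {
        --k;
      } else {
        break;
      }
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < (double)q) ++k;
    const int p = v[k];
    d[q] = w2 * (q - p) * (q - p) + f[p];
  }
}

// Exact Euclidean distance (mm) from every voxel to the nearest TRUE voxel
// of `mask`, on an anisotropic grid with voxel dimensions `spacing`.
// [[Rcpp::export]]
NumericVector edt_cpp(LogicalVector mask, IntegerVector dim, NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dim");
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = mask[i] ? 0.0 : CS_BIG;

  const int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along x
  for (int kk = 0; kk < nz; ++kk)
    for (int jj = 0; jj < ny; ++jj) {
      const R_xlen_t base = (R_xlen_t)kk * nx * ny + (R_xlen_t)jj * nx;
      for (int ii = 0; ii < nx; ++ii) f[ii] = out[base + ii];
      f.resize(nx); d.resize(nx);
      dt1d(f, d, v, z, spacing[0]);
      for (int ii = 0; ii < nx; ++ii) out[base + ii] = d[ii];
      f.resize(nmax); d.resize(nmax);
    }
  // pass along y
  for (int kk = 0; kk < nz; ++kk)
    for (int ii = 0; ii < nx; ++ii) {
      const R_xlen_t base = (R_xlen_t)kk * nx * ny + ii;
      for (int jj = 0; jj < ny; ++jj) f[jj] = out[base + (R_xlen_t)jj * nx];
      f.resize(ny); d.resize(ny);
      dt1d(f, d, v, z, spacing[1]);
      for (int jj = 0; jj < ny; ++jj) out[base + (R_xlen_t)jj * nx] = d[jj];
      f.resize(nmax); d.resize(nmax);
    }
  // pass along z
  const R_xlen_t nxy = (R_xlen_t)nx * ny;
  for (int jj = 0; jj < ny; ++jj)
    for (int ii = 0; ii < nx; ++ii) {
      const R_xlen_t base = (R_xlen_t)jj * nx + ii;
      for (int kk = 0; kk < nz; ++kk) f[kk] = out[base + (R_xlen_t)kk * nxy];
      f.resize(nz); d.resize(nz);
      dt1d(f, d, v, z, spacing[2]);
      for (int kk = 0; kk < nz; ++kk) out[base + (R_xlen_t)kk * nxy] = d[kk];
      f.resize(nmax); d.resize(nmax);
    }

  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = (out[i] >= CS_BIG) ? R_PosInf : std::sqrt(out[i]);
  return out;
}
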