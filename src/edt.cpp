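#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Exact squared Euclidean distance transform (lower-envelope-of-parabolas
// algorithm), separable over the three axes with per-axis physical sample
// spacing, so anisotropic voxels give true mm distances.

static const double INF = std::numeric_limits<double>::infinity();

// 1D squared distance transform of sampled function f at abscissae i*s.
// Entries with f == INF carry no parabola (lines with no feature yet).
static void dt1d(const double *f, double *d, int n, double s,
                 std::vector<int> &v, std::vector<double> &z) {
  int q0 = 0;
  while (q0 < n && f[q0] == INF) q0++;
  if (q0 == n) {
    for (int q = 0; q < n; q++) d[q] = INF;
    return;
  }
  int k = 0;
  v[0] = q0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = q0 + 1; q < n; q++) {
    if (f[q] == INF) continue;
    double xq = q * s;
    double inter;
    for (;;) {
      double xv = v[k] * s;
      inter = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2.0 * (xq - xv));
      if (inter <= z[k]) k--; else break;
    }
    k++;
    v[k] = q;
    z[k] = inter;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    double xq = q * s;
    while (z[k + 1] < xq) k++;
    double xv = v[k] * s;
    d[q] = (xq - xv) * (xq - xv) + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericVector edt_sq_cpp(LogicalVector feature, IntegerVector dims,
                         NumericVector spacing) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector g(n);
  for (R_xlen_t i = 0; i < n; i++) g[i] = feature[i] ? 0.0 : INF;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along x
  for (int kz = 0; kz < nz; kz++)
    for (int ky = 0; ky < ny; ky++) {
      R_xlen_t base = (R_xlen_t)nx * (ky + (R_xlen_t)ny * kz);
      for (int i = 0; i < nx; i++) f[i] = g[base + i];
      dt1d(f.data(), d.data(), nx, spacing[0], v, z);
      for (int i = 0; i < nx; i++) g[base + i] = d[i];
    }
  // pass along y
  for (int kz = 0; kz < nz; kz++)
    for (int kx = 0; kx < nx; kx++) {
      R_xlen_t base = kx + (R_xlen_t)nx * ny * kz;
      for (int i = 0; i < ny; i++) f[i] = g[base + (R_xlen_t)nx * i];
      dt1d(f.data(), d.data(), ny, spacing[1], v, z);
      for (int i = 0; i < ny; i++) g[base + (R_xlen_t)nx * i] = d[i];
    }
  // pass along z
  R_xlen_t nxy = (R_xlen_t)nx * ny;
  for (int ky = 0; ky < ny; ky++)
    for (int kx = 0; kx < nx; kx++) {
      R_xlen_t base = kx + (R_xlen_t)nx * ky;
      for (int i = 0; i < nz; i++) f[i] = g[base + nxy * i];
      dt1d(f.data(), d.data(), nz, spacing[2], v, z);
      for (int i = 0; i < nz; i++) g[base + nxy * i] = d[i];
    }
  return g;
}
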