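#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Sampling kernels shared by displacement fields, scalar images and cubic
// B-spline lattices. Points are world coordinates in mm; rasters are
// column-major with x fastest, matching R array layout.

static inline int clampi(int i, int lo, int hi) {
  return i < lo ? lo : (i > hi ? hi : i);
}

// Trilinear sampling of an ncomp-channel raster at arbitrary points.
// Out-of-domain points are edge-clamped.
// values: length nx*ny*nz*ncomp, channel slowest.
// [[Rcpp::export]]
NumericMatrix trilinear_sample_cpp(NumericMatrix pts, NumericVector values,
                                   IntegerVector dims, NumericVector origin,
                                   NumericVector spacing, int ncomp) {
  int n = pts.nrow();
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  NumericMatrix out(n, ncomp);
  for (int p = 0; p < n; p++) {
    double u = (pts(p, 0) - origin[0]) / spacing[0];
    double v = (pts(p, 1) - origin[1]) / spacing[1];
    double w = (pts(p, 2) - origin[2]) / spacing[2];
    int i0 = (int)std::floor(u), j0 = (int)std::floor(v), k0 = (int)std::floor(w);
    double fx = u - i0, fy = v - j0, fz = w - k0;
    // clamp cell so both corners exist; adjust fraction to keep continuity
    if (i0 < 0) { i0 = 0; fx = 0.0; }
    if (i0 > nx - 2) { i0 = nx - 2; fx = 1.0; }
    if (j0 < 0) { j0 = 0; fy = 0.0; }
    if (j0 > ny - 2) { j0 = ny - 2; fy = 1.0; }
    if (k0 < 0) { k0 = 0; fz = 0.0; }
    if (k0 > nz - 2) { k0 = nz - 2; fz = 1.0; }
    if (nx == 1) { i0 = 0; fx = 0.0; }
    if (ny == 1) { j0 = 0; fy = 0.0; }
    if (nz == 1) { k0 = 0; fz = 0.0; }
    double wx[2] = {1.0 - fx, fx}, wy[2] = {1.0 - fy, fy}, wz[2] = {1.0 - fz, fz};
    for (int c = 0; c < ncomp; c++) {
      double acc = 0.0;
      for (int dz = 0; dz < 2; dz++) {
        int kk = clampi(k0 + dz, 0, nz - 1);
        for (int dy = 0; dy < 2; dy++) {
          int jj = clampi(j0 + dy, 0, ny - 1);
          double wyz = wy[dy] * wz[dz];
          if (wyz == 0.0) continue;
          for (int dx = 0; dx < 2; dx++) {
            if (wx[dx] == 0.0) continue;
            int ii = clampi(i0 + dx, 0, nx - 1);
            R_xlen_t lin = ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk) + nvox * c;
            acc += wx[dx] * wyz * values[lin];
          }
        }
      }
      out(p, c) = acc;
    }
  }
  return out;
}

static inline void cubic_weights(double t, double *b) {
  double t2 = t * t, t3 = t2 * t;
  b[0] = (1.0 - 3.0 * t + 3.0 * t2 - t3) / 6.0;
  b[1] = (4.0 - 6.0 * t2 + 3.0 * t3) / 6.0;
  b[2] = (1.0 + 3.0 * t + 3.0 * t2 - 3.0 * t3) / 6.0;
  b[3] = t3 / 6.0;
}

static inline int mirrori(int i, int n) {
  if (n == 1) return 0;
  int period = 2 * (n - 1);
  i = ((i % period) + period) % period;
  return i < n ? i : period - i;
}

// Cubic B-spline evaluation on a coefficient lattice at arbitrary points.
// zero_outside = true: missing lattice coefficients contribute zero
// (free-form deformation convention); false: mirror-reflected indices
// (image interpolation convention, matching the mirror-boundary prefilter).
// [[Rcpp::export]]
NumericMatrix bspline_sample_cpp(NumericMatrix pts, NumericVector coef,
                                 IntegerVector dims, NumericVector origin,
                                 NumericVector spacing, int ncomp,
                                 bool zero_outside) {
  int n = pts.nrow();
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  NumericMatrix out(n, ncomp);
  double bx[4], by[4], bz[4];
  for (int p = 0; p < n; p++) {
    double u = (pts(p, 0) - origin[0]) / spacing[0];
    double v = (pts(p, 1) - origin[1]) / spacing[1];
    double w = (pts(p, 2) - origin[2]) / spacing[2];
    int i0 = (int)std::floor(u), j0 = (int)std::floor(v), k0 = (int)std::floor(w);
    cubic_weights(u - i0, bx);
    cubic_weights(v - j0, by);
    cubic_weights(w - k0, bz);
    for (int c = 0; c < ncomp; c++) {
      double acc = 0.0;
      for (int dz = 0; dz < 4; dz++) {
        int kk = k0 - 1 + dz;
        if (zero_outside && (kk < 0 || kk >= nz)) continue;
        kk = zero_outside ? kk : mirrori(kk, nz);
        for (int dy = 0; dy < 4; dy++) {
          int jj = j0 - 1 + dy;
          if (zero_outside && (jj < 0 || jj >= ny)) continue;
          jj = zero_outside ? jj : mirrori(jj, ny);
          double wyz = by[dy] * bz[dz];
          for (int dx = 0; dx < 4; dx++) {
            int ii = i0 - 1 + dx;
            if (zero_outside && (ii < 0 || ii >= nx)) continue;
            ii = zero_outside ? ii : mirrori(ii, nx);
            R_xlen_t lin = ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk) + nvox * c;
            acc += bx[dx] * wyz * coef[lin];
          }
        }
      }
      out(p, c) = acc;
    }
  }
  return out;
}

// In-place causal/anticausal recursive prefilter turning samples into cubic
// B-spline interpolation coefficients (pole sqrt(3) - 2), mirror boundaries.
static void prefilter_line(double *c, int n) {
  const double z = std::sqrt(3.0) - 2.0;
  const double gain = 6.0; // (1 - z) * (1 - 1/z)
  if (n == 1) return;
  // causal initialization: sum over mirrored signal
  double sum = c[0];
  double zn = z;
  int horizon = (int)std::ceil(std::log(1e-14) / std::log(std::fabs(z)));
  if (horizon > n - 1) horizon = n - 1;
  for (int i = 1; i <= horizon; i++) {
    sum += zn * c[i];
    zn *= z;
  }
  c[0] = sum;
  for (int i = 1; i < n; i++) c[i] += z * c[i - 1];
  // anticausal initialization (mirror)
  c[n - 1] = (z / (z * z - 1.0)) * (z * c[n - 2] + c[n - 1]);
  for (int i = n - 2; i >= 0; i--) c[i] = z * (c[i + 1] - c[i]);
  for (int i = 0; i < n; i++) c[i] *= gain;
}

// [[Rcpp::export]]
NumericVector bspline_prefilter_cpp(NumericVector values, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector c = clone(values);
  std::vector<double> line(std::max(nx, std::max(ny, nz)));
  R_xlen_t nxy = (R_xlen_t)nx * ny;
  for (int kz = 0; kz < nz; kz++)
    for (int ky = 0; ky < ny; ky++) {
      R_xlen_t base = (R_xlen_t)nx * ky + nxy * kz;
      prefilter_line(&c[base], nx); // contiguous along x
    }
  for (int kz = 0; kz < nz; kz++)
    for (int kx = 0; kx < nx; kx++) {
      R_xlen_t base = kx + nxy * kz;
      for (int i = 0; i < ny; i++) line[i] = c[base + (R_xlen_t)nx * i];
      prefilter_line(line.data(), ny);
      for (int i = 0; i < ny; i++) c[base + (R_xlen_t)nx * i] = line[i];
    }
  for (int ky = 0; ky < ny; ky++)
    for (int kx = 0; kx < nx; kx++) {
      R_xlen_t base = kx + (R_xlen_t)nx * ky;
      for (int i = 0; i < nz; i++) line[i] = c[base + nxy * i];
      prefilter_line(line.data(), nz);
      for (int i = 0; i < nz; i++) c[base + nxy * i] = line[i];
    }
  return c;
}
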