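#include <Rcpp.h>
#include "interp.h"
using namespace Rcpp;

// Evaluate a cubic B-spline free-form displacement at world point (x,y,z).
// coef: (ncx*ncy*ncz*3) array, control grid origin/spacing in mm.
static inline void ffd_displacement(const double* coef, int ncx, int ncy, int ncz,
                                    const double* corig, const double* cspac,
                                    double x, double y, double z, double* u) {
  u[0] = u[1] = u[2] = 0.0;
  double tx = (x - corig[0]) / cspac[0];
  double ty = (y - corig[1]) / cspac[1];
  double tz = (z - corig[2]) / cspac[2];
  int ix = (int)std::floor(tx), iy = (int)std::floor(ty), iz = (int)std::floor(tz);
  for (int mz = iz - 1; mz <= iz + 2; ++mz) {
    if (mz < 0 || mz >= ncz) continue;
    double wz = bspline3(tz - mz);
    if (wz == 0.0) continue;
    for (int my = iy - 1; my <= iy + 2; ++my) {
      if (my < 0 || my >= ncy) continue;
      double wyz = wz * bspline3(ty - my);
      if (wyz == 0.0) continue;
      for (int mx = ix - 1; mx <= ix + 2; ++mx) {
        if (mx < 0 || mx >= ncx) continue;
        double w = wyz * bspline3(tx - mx);
        if (w == 0.0) continue;
        R_xlen_t base = (R_xlen_t)mx + (R_xlen_t)ncx * ((R_xlen_t)my + (R_xlen_t)ncy * mz);
        R_xlen_t n3 = (R_xlen_t)ncx * ncy * ncz;
        u[0] += w * coef[base];
        u[1] += w * coef[base + n3];
        u[2] += w * coef[base + 2 * n3];
      }
    }
  }
}

// Resample a moving volume onto a fixed lattice through y = Aff(x + u(x)),
// where u is an optional B-spline displacement defined on the fixed domain.
// label_mode: nearest-neighbour lookup instead of trilinear.
// [[Rcpp::export(name = ".resample_cpp")]]
NumericVector resample_cpp(NumericVector moving, NumericVector mspacing,
                           NumericVector morigin, IntegerVector fdim,
                           NumericVector fspacing, NumericVector forigin,
                           NumericMatrix A, NumericVector t, NumericVector cen,
                           Nullable<NumericVector> bspline_coef,
                           Nullable<IntegerVector> ctrl_dim,
                           Nullable<NumericVector> ctrl_origin,
                           Nullable<NumericVector> ctrl_spacing,
                           bool label_mode) {
  Grid3 M(moving, mspacing, morigin);
  AffineMap T(A, t, cen);
  int nx = fdim[0], ny = fdim[1], nz = fdim[2];
  NumericVector out((R_xlen_t)nx * ny * nz);
  out.attr("dim") = IntegerVector::create(nx, ny, nz);
  const double* coef = nullptr;
  int ncx = 0, ncy = 0, ncz = 0;
  double corig[3] = {0, 0, 0}, cspac[3] = {1, 1, 1};
  if (bspline_coef.isNotNull()) {
    NumericVector cf(bspline_coef);
    IntegerVector cd(ctrl_dim);
    NumericVector co(ctrl_origin), cs(ctrl_spacing);
    coef = cf.begin();
    ncx = cd[0]; ncy = cd[1]; ncz = cd[2];
    for (int r = 0; r < 3; ++r) { corig[r] = co[r]; cspac[r] = cs[r]; }
  }
  double* o = out.begin();
  for (int k = 0; k < nz; ++k) {
    double wz = forigin[2] + k * fspacing[2];
    for (int j = 0; j < ny; ++j) {
      double wy = forigin[1] + j * fspacing[1];
      R_xlen_t row = (R_xlen_t)nx * ((R_xlen_t)j + (R_xlen_t)ny * k);
      for (int i = 0; i < nx; ++i) {
        double wx = forigin[0] + i * fspacing[0];
        double px = wx, py = wy, pz = wz;
        if (coef) {
          double u[3];
          ffd_displacement(coef, ncx, ncy, ncz, corig, cspac, wx, wy, wz, u);
          px += u[0]; py += u[1]; pz += u[2];
        }
        double qx, qy, qz;
        T.apply(px, py, pz, qx, qy, qz);
        o[row + i] = label_mode ? M.nearest(qx, qy, qz) : M.trilinear(qx, qy, qz);
      }
    }
  }
  return out;
}

// Separable Gaussian smoothing with per-axis sigma in voxels (truncated 3 sigma).
// [[Rcpp::export(name = ".gaussian_smooth3_cpp")]]
NumericVector gaussian_smooth3_cpp(NumericVector arr, NumericVector sigma_vox) {
  IntegerVector d = arr.attr("dim");
  int nx = d[0], ny = d[1], nz = d[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> buf(arr.begin(), arr.end()), tmp(n);
  int strides[3] = {1, nx, nx * ny};
  int dims[3] = {nx, ny, nz};
  for (int ax = 0; ax < 3; ++ax) {
    double s = sigma_vox[ax];
    if (s <= 0) continue;
    int r = std::max(1, (int)std::ceil(3.0 * s));
    std::vector<double> w(2 * r + 1);
    double sum = 0;
    for (int q = -r; q <= r; ++q) { w[q + r] = std::exp(-0.5 * q * q / (s * s)); sum += w[q + r]; }
    for (auto& x : w) x /= sum;
    int st = strides[ax], len = dims[ax];
    R_xlen_t nlines = n / len;
    for (R_xlen_t line = 0; line < nlines; ++line) {
      // decompose line index into the two non-axis coordinates
      R_xlen_t rem = line, idx = 0, mult = 1;
      for (int a2 = 0; a2 < 3; ++a2) {
        if (a2 == ax) continue;
        R_xlen_t c = rem % dims[a2];
        rem /= dims[a2];
        idx += c * strides[a2];
        (void)mult;
      }
      for (int p = 0; p < len; ++p) {
        double acc = 0, wsum = 0;
        for (int q = -r; q <= r; ++q) {
          int pp = p + q;
          if (pp < 0 || pp >= len) continue;
          acc += w[q + r] * buf[idx + (R_xlen_t)pp * st];
          wsum += w[q + r];
        }
        tmp[idx + (R_xlen_t)p * st] = acc / wsum;
      }
    }
    buf.swap(tmp);
  }
  NumericVector out(buf.begin(), buf.end());
  out.attr("dim") = d;
  return out;
}

// In-plane block-average downsampling (image mode). Slice axis untouched.
// [[Rcpp::export(name = ".block_downsample_image_cpp")]]
NumericVector block_downsample_image_cpp(NumericVector arr, int factor) {
  IntegerVector d = arr.attr("dim");
  int nx = d[0], ny = d[1], nz = d[2];
  int mx = nx / factor, my = ny / factor;
  NumericVector out((R_xlen_t)mx * my * nz);
  out.attr("dim") = IntegerVector::create(mx, my, nz);
  const double* v = arr.begin();
  double* o = out.begin();
  double inv = 1.0 / (factor * factor);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < my; ++j)
      for (int i = 0; i < mx; ++i) {
        double acc = 0;
        for (int b = 0; b < factor; ++b)
          for (int a = 0; a < factor; ++a)
            acc += v[(R_xlen_t)(i * factor + a) +
                     (R_xlen_t)nx * ((R_xlen_t)(j * factor + b) + (R_xlen_t)ny * k)];
        o[(R_xlen_t)i + (R_xlen_t)mx * ((R_xlen_t)j + (R_xlen_t)my * k)] = acc * inv;
      }
  return out;
}

// In-plane block-mode downsampling for label maps; ties -> lowest code.
// [[Rcpp::export(name = ".block_downsample_label_cpp")]]
IntegerVector block_downsample_label_cpp(IntegerVector arr, int factor) {
  IntegerVector d = arr.attr("dim");
  int nx = d[0], ny = d[1], nz = d[2];
  int mx = nx / factor, my = ny / factor;
  IntegerVector out((R_xlen_t)mx * my * nz);
  out.attr("dim") = IntegerVector::create(mx, my, nz);
  const int* v = arr.begin();
  int* o = out.begin();
  std::vector<int> codes(factor * factor), counts(factor * factor);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < my; ++j)
      for (int i = 0; i < mx; ++i) {
        int ncode = 0;
        for (int b = 0; b < factor; ++b)
          for (int a = 0; a < factor; ++a) {
            int c = v[(R_xlen_t)(i * factor + a) +
                      (R_xlen_t)nx * ((R_xlen_t)(j * factor + b) + (R_xlen_t)ny * k)];
            int found = -1;
            for (int q = 0; q < ncode; ++q) if (codes[q] == c) { found = q; break; }
            if (found >= 0) counts[found]++;
            else { codes[ncode] = c; counts[ncode] = 1; ncode++; }
          }
        int best = codes[0], bestn = counts[0];
        for (int q = 1; q < ncode; ++q)
          if (counts[q] > bestn || (counts[q] == bestn && codes[q] < best)) {
            best = codes[q]; bestn = counts[q];
          }
        o[(R_xlen_t)i + (R_xlen_t)mx * ((R_xlen_t)j + (R_xlen_t)my * k)] = best;
      }
  return out;
}
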