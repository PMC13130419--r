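#pragma once
#include <Rcpp.h>
#include <cmath>

// A 3D scalar grid on a regular lattice. Index (i,j,k) is 0-based and
// column-major (x fastest). World coordinate of voxel centre (i,j,k) is
// origin + index * spacing, per axis.
struct Grid3 {
  const double* v;
  int nx, ny, nz;
  double sx, sy, sz;
  double ox, oy, oz;

  Grid3(const Rcpp::NumericVector& arr, const Rcpp::NumericVector& spacing,
        const Rcpp::NumericVector& origin) {
    Rcpp::IntegerVector d = arr.attr("dim");
    if (d.size() != 3) Rcpp::stop("expected a 3D array");
    v = arr.begin();
    nx = d[0]; ny = d[1]; nz = d[2];
    sx = spacing[0]; sy = spacing[1]; sz = spacing[2];
    ox = origin[0]; oy = origin[1]; oz = origin[2];
  }

  inline double at(int i, int j, int k) const {
    return v[(R_xlen_t)i + (R_xlen_t)nx * ((R_xlen_t)j + (R_xlen_t)ny * k)];
  }

  // Trilinear interpolation at a world point; 0 outside the volume.
  inline double trilinear(double wx, double wy, double wz) const {
    double fx = (wx - ox) / sx, fy = (wy - oy) / sy, fz = (wz - oz) / sz;
    if (fx < -0.5 || fy < -0.5 || fz < -0.5 ||
        fx > nx - 0.5 || fy > ny - 0.5 || fz > nz - 0.5) return 0.0;
    int i0 = (int)std::floor(fx), j0 = (int)std::floor(fy), k0 = (int)std::floor(fz);
    double ax = fx - i0, ay = fy - j0, az = fz - k0;
    double out = 0.0;
    for (int dk = 0; dk <= 1; ++dk) {
      int k = k0 + dk; if (k < 0 || k >= nz) continue;
      double wkz = dk ? az : 1.0 - az;
      for (int dj = 0; dj <= 1; ++dj) {
        int j = j0 + dj; if (j < 0 || j >= ny) continue;
        double wjy = dj ? ay : 1.0 - ay;
        for (int di = 0; di <= 1; ++di) {
          int i = i0 + di; if (i < 0 || i >= nx) continue;
          double wix = di ? ax : 1.0 - ax;
          out += wkz * wjy * wix * at(i, j, k);
        }
      }
    }
    return out;
  }

  // Nearest-neighbour lookup at a world point; 0 outside.
  inline double nearest(double wx, double wy, double wz) const {
    int i = (int)std::lround((wx - ox) / sx);
    int j = (int)std::lround((wy - oy) / sy);
    int k = (int)std::lround((wz - oz) / sz);
    if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) return 0.0;
    return at(i, j, k);
  }

  inline bool inside(double wx, double wy, double wz) const {
    double fx = (wx - ox) / sx, fy = (wy - oy) / sy, fz = (wz - oz) / sz;
    return fx >= 0 && fy >= 0 && fz >= 0 &&
           fx <= nx - 1 && fy <= ny - 1 && fz <= nz - 1;
  }
};

// Affine map y = A (x - c) + c + t applied to a world point.
struct AffineMap {
  double A[9]; // row-major 3x3
  double t[3], c[3];
  AffineMap(const Rcpp::NumericMatrix& Am, const Rcpp::NumericVector& tv,
            const Rcpp::NumericVector& cv) {
    for (int r = 0; r < 3; ++r)
      for (int s = 0; s < 3; ++s) A[3 * r + s] = Am(r, s);
    for (int r = 0; r < 3; ++r) { t[r] = tv[r]; c[r] = cv[r]; }
  }
  inline void apply(double x, double y, double z,
                    double& ox_, double& oy_, double& oz_) const {
    double dx = x - c[0], dy = y - c[1], dz = z - c[2];
    ox_ = A[0] * dx + A[1] * dy + A[2] * dz + c[0] + t[0];
    oy_ = A[3] * dx + A[4] * dy + A[5] * dz + c[1] + t[1];
    oz_ = A[6] * dx + A[7] * dy + A[8] * dz + c[2] + t[2];
  }
};

// Cubic B-spline kernel, |u| <= 2 support.
inline double bspline3(double u) {
  double a = std::fabs(u);
  if (a >= 2.0) return 0.0;
  if (a < 1.0) return (4.0 - 6.0 * a * a + 3.0 * a * a * a) / 6.0;
  double b = 2.0 - a;
  return b * b * b / 6.0;
}
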