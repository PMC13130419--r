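#include <Rcpp.h>
#include <random>
#include "interp.h"
using namespace Rcpp;

// Normalised cross-correlation of two equal-length vectors.
// [[Rcpp::export(name = ".ncc_cpp")]]
double ncc_cpp(NumericVector a, NumericVector b) {
  R_xlen_t n = a.size();
  if (n != b.size()) stop("length mismatch");
  double ma = 0, mb = 0;
  for (R_xlen_t i = 0; i < n; ++i) { ma += a[i]; mb += b[i]; }
  ma /= n; mb /= n;
  double sab = 0, saa = 0, sbb = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    double da = a[i] - ma, db = b[i] - mb;
    sab += da * db; saa += da * da; sbb += db * db;
  }
  if (saa <= 0 || sbb <= 0) return 0.0;
  return sab / std::sqrt(saa * sbb);
}

static void rigid_to_matrix(const double* p, double* A) {
  // p = rx, ry, rz in degrees; A = Rz * Ry * Rx, row-major.
  double d2r = M_PI / 180.0;
  double cx = std::cos(p[0] * d2r), sx = std::sin(p[0] * d2r);
  double cy = std::cos(p[1] * d2r), sy = std::sin(p[1] * d2r);
  double cz = std::cos(p[2] * d2r), sz = std::sin(p[2] * d2r);
  A[0] = cz * cy;  A[1] = cz * sy * sx - sz * cx;  A[2] = cz * sy * cx + sz * sx;
  A[3] = sz * cy;  A[4] = sz * sy * sx + cz * cx;  A[5] = sz * sy * cx - cz * sx;
  A[6] = -sy;      A[7] = cy * sx;                 A[8] = cy * cx;
}

struct SampleSet {
  std::vector<double> wx, wy, wz, f;
};

static void draw_samples(std::mt19937& rng, const Grid3& F, int n, SampleSet& S) {
  std::uniform_int_distribution<int> ux(0, F.nx - 1), uy(0, F.ny - 1), uz(0, F.nz - 1);
  S.wx.resize(n); S.wy.resize(n); S.wz.resize(n); S.f.resize(n);
  for (int s = 0; s < n; ++s) {
    int i = ux(rng), j = uy(rng), k = uz(rng);
    S.wx[s] = F.ox + i * F.sx;
    S.wy[s] = F.oy + j * F.sy;
    S.wz[s] = F.oz + k * F.sz;
    S.f[s] = F.at(i, j, k);
  }
}

// NCC of fixed samples vs moving values sampled through a linear map.
static double ncc_linear(const SampleSet& S, const Grid3& M, const double* params,
                         bool affine, const double* cen) {
  int n = (int)S.f.size();
  double A[9], t[3];
  if (affine) { for (int q = 0; q < 9; ++q) A[q] = params[q]; for (int q = 0; q < 3; ++q) t[q] = params[9 + q]; }
  else { rigid_to_matrix(params, A); for (int q = 0; q < 3; ++q) t[q] = params[3 + q]; }
  double mf = 0, mm = 0;
  std::vector<double> mv(n);
  for (int s = 0; s < n; ++s) {
    double dx = S.wx[s] - cen[0], dy = S.wy[s] - cen[1], dz = S.wz[s] - cen[2];
    double qx = A[0] * dx + A[1] * dy + A[2] * dz + cen[0] + t[0];
    double qy = A[3] * dx + A[4] * dy + A[5] * dz + cen[1] + t[1];
    double qz = A[6] * dx + A[7] * dy + A[8] * dz + cen[2] + t[2];
    mv[s] = M.trilinear(qx, qy, qz);
    mf += S.f[s]; mm += mv[s];
  }
  mf /= n; mm /= n;
  double sab = 0, saa = 0, sbb = 0;
  for (int s = 0; s < n; ++s) {
    double da = S.f[s] - mf, db = mv[s] - mm;
    sab += da * db; saa += da * da; sbb += db * db;
  }
  if (saa <= 0 || sbb <= 0) return 0.0;
  return sab / std::sqrt(saa * sbb);
}

// Stochastic gradient ascent on NCC over linear transform parameters,
// finite-difference gradient in scaled parameter space, decaying gain
// (adaptive stochastic gradient descent family).
// mode: "rigid" (6 params: rot deg x3, trans mm x3) or
//       "affine" (12 params: row-major 3x3 matrix + trans mm).
// [[Rcpp::export(name = ".register_linear_cpp")]]
List register_linear_cpp(NumericVector fixed, NumericVector fspacing, NumericVector forigin,
                         NumericVector moving, NumericVector mspacing, NumericVector morigin,
                         std::string mode, NumericVector init, NumericVector cen,
                         int iterations, int n_samples, double step0, int seed) {
  Grid3 F(fixed, fspacing, forigin);
  Grid3 M(moving, mspacing, morigin);
  bool affine = (mode == "affine");
  int np = affine ? 12 : 6;
  std::vector<double> p(init.begin(), init.end());
  if ((int)p.size() != np) stop("init has wrong length for mode");
  std::vector<double> sc(np);
  if (affine) { for (int q = 0; q < 9; ++q) sc[q] = 0.01; for (int q = 9; q < 12; ++q) sc[q] = 1.0; }
  else { for (int q = 0; q < 3; ++q) sc[q] = 1.0; for (int q = 3; q < 6; ++q) sc[q] = 1.0; }
  double cenv[3] = {cen[0], cen[1], cen[2]};
  std::mt19937 rng(seed);
  SampleSet S;
  const double eps = 0.05, Again = 20.0, alpha = 0.602;
  std::vector<double> g(np), pp(p);
  for (int it = 0; it < iterations; ++it) {
    draw_samples(rng, F, n_samples, S);
    double gn = 0;
    for (int q = 0; q < np; ++q) {
      pp = p;
      pp[q] = p[q] + eps * sc[q];
      double up = ncc_linear(S, M, pp.data(), affine, cenv);
      pp[q] = p[q] - eps * sc[q];
      double dn = ncc_linear(S, M, pp.data(), affine, cenv);
      g[q] = (up - dn) / (2.0 * eps);
      gn += g[q] * g[q];
    }
    gn = std::sqrt(gn);
    if (gn < 1e-12) continue;
    double gain = step0 * std::pow(Again + 1.0, alpha) / std::pow(Again + 1.0 + it, alpha);
    for (int q = 0; q < np; ++q) p[q] += gain * sc[q] * g[q] / gn;
  }
  // final NCC on a large deterministic sample for reporting
  draw_samples(rng, F, std::min((R_xlen_t)20000, (R_xlen_t)F.nx * F.ny * F.nz), S);
  double final_ncc = ncc_linear(S, M, p.data(), affine, cenv);
  return List::create(_["params"] = NumericVector(p.begin(), p.end()),
                      _["ncc"] = final_ncc);
}

// B-spline FFD registration: gradient ascent on sampled NCC over control-point
// displacements (fixed-domain FFD composed with a fixed linear map:
// y = Aff(x + u(x))). Analytic chain-rule gradient.
// [[Rcpp::export(name = ".register_bspline_cpp")]]
List register_bspline_cpp(NumericVector fixed, NumericVector fspacing, NumericVector forigin,
                          NumericVector moving, NumericVector mspacing, NumericVector morigin,
                          NumericMatrix A, NumericVector t, NumericVector cen,
                          IntegerVector ctrl_dim, NumericVector ctrl_origin,
                          NumericVector ctrl_spacing, NumericVector init_coef,
                          int iterations, int n_samples, double step_mm, int seed) {
  Grid3 F(fixed, fspacing, forigin);
  Grid3 M(moving, mspacing, morigin);
  AffineMap T(A, t, cen);
  int ncx = ctrl_dim[0], ncy = ctrl_dim[1], ncz = ctrl_dim[2];
  R_xlen_t n3 = (R_xlen_t)ncx * ncy * ncz;
  std::vector<double> coef(init_coef.begin(), init_coef.end());
  if ((R_xlen_t)coef.size() != 3 * n3) stop("init_coef has wrong length");
  double corig[3] = {ctrl_origin[0], ctrl_origin[1], ctrl_origin[2]};
  double cspac[3] = {ctrl_spacing[0], ctrl_spacing[1], ctrl_spacing[2]};
  std::mt19937 rng(seed);
  SampleSet S;
  std::vector<double> grad(3 * n3);
  std::vector<double> mv, wgt;
  const double Again = 20.0, alpha = 0.602;
  double hx = 0.5 * mspacing[0], hy = 0.5 * mspacing[1], hz = 0.5 * mspacing[2];
  for (int it = 0; it < iterations; ++it) {
    draw_samples(rng, F, n_samples, S);
    int n = n_samples;
    mv.assign(n, 0.0);
    std::vector<double> qxs(n), qys(n), qzs(n);
    double mf = 0, mm = 0;
    for (int s = 0; s < n; ++s) {
      double px = S.wx[s], py = S.wy[s], pz = S.wz[s], u[3];
      // inline FFD evaluation
      u[0] = u[1] = u[2] = 0.0;
      {
        double tx = (px - corig[0]) / cspac[0];
        double ty = (py - corig[1]) / cspac[1];
        double tz = (pz - corig[2]) / cspac[2];
        int ix = (int)std::floor(tx), iy = (int)std::floor(ty), iz = (int)std::floor(tz);
        for (int mz = iz - 1; mz <= iz + 2; ++mz) {
          if (mz < 0 || mz >= ncz) continue;
          double wz = bspline3(tz - mz);
          for (int my = iy - 1; my <= iy + 2; ++my) {
            if (my < 0 || my >= ncy) continue;
            double wyz = wz * bspline3(ty - my);
            for (int mx = ix - 1; mx <= ix + 2; ++mx) {
              if (mx < 0 || mx >= ncx) continue;
              double w = wyz * bspline3(tx - mx);
              R_xlen_t base = (R_xlen_t)mx + (R_xlen_t)ncx * ((R_xlen_t)my + (R_xlen_t)ncy * mz);
              u[0] += w * coef[base];
              u[1] += w * coef[base + n3];
              u[2] += w * coef[base + 2 * n3];
            }
          }
        }
      }
      double qx, qy, qz;
      T.apply(px + u[0], py + u[1], pz + u[2], qx, qy, qz);
      qxs[s] = qx; qys[s] = qy; qzs[s] = qz;
      mv[s] = M.trilinear(qx, qy, qz);
      mf += S.f[s]; mm += mv[s];
    }
    mf /= n; mm /= n;
    double sab = 0, saa = 0, sbb = 0;
    for (int s = 0; s < n; ++s) {
      double da = S.f[s] - mf, db = mv[s] - mm;
      sab += da * db; saa += da * da; sbb += db * db;
    }
    if (saa <= 0 || sbb <= 0) continue;
    double denom = std::sqrt(saa * sbb), ncc = sab / denom;
    std::fill(grad.begin(), grad.end(), 0.0);
    for (int s = 0; s < n; ++s) {
      double w_s = (S.f[s] - mf) / denom - ncc * (mv[s] - mm) / sbb;
      // moving-image gradient at warped point (central differences)
      double gx = (M.trilinear(qxs[s] + hx, qys[s], qzs[s]) -
                   M.trilinear(qxs[s] - hx, qys[s], qzs[s])) / (2 * hx);
      double gy = (M.trilinear(qxs[s], qys[s] + hy, qzs[s]) -
                   M.trilinear(qxs[s], qys[s] - hy, qzs[s])) / (2 * hy);
      double gz = (M.trilinear(qxs[s], qys[s], qzs[s] + hz) -
                   M.trilinear(qxs[s], qys[s], qzs[s] - hz)) / (2 * hz);
      // chain through the linear map: d m / d u = grad(M)^T * A
      double cx = gx * T.A[0] + gy * T.A[3] + gz * T.A[6];
      double cy = gx * T.A[1] + gy * T.A[4] + gz * T.A[7];
      double cz = gx * T.A[2] + gy * T.A[5] + gz * T.A[8];
      // scatter to the control points supporting this sample
      double tx = (S.wx[s] - corig[0]) / cspac[0];
      double ty = (S.wy[s] - corig[1]) / cspac[1];
      double tz = (S.wz[s] - corig[2]) / cspac[2];
      int ix = (int)std::floor(tx), iy = (int)std::floor(ty), iz = (int)std::floor(tz);
      for (int mz = iz - 1; mz <= iz + 2; ++mz) {
        if (mz < 0 || mz >= ncz) continue;
        double wz = bspline3(tz - mz);
        for (int my = iy - 1; my <= iy + 2; ++my) {
          if (my < 0 || my >= ncy) continue;
          double wyz = wz * bspline3(ty - my);
          for (int mx = ix - 1; mx <= ix + 2; ++mx) {
            if (mx < 0 || mx >= ncx) continue;
            double w = w_s * wyz * bspline3(tx - mx);
            R_xlen_t base = (R_xlen_t)mx + (R_xlen_t)ncx * ((R_xlen_t)my + (R_xlen_t)ncy * mz);
            grad[base] += w * cx;
            grad[base + n3] += w * cy;
            grad[base + 2 * n3] += w * cz;
          }
        }
      }
    }
    double gmax = 0;
    for (double gq : grad) gmax = std::max(gmax, std::fabs(gq));
    if (gmax < 1e-14) continue;
    double gain = step_mm * std::pow(Again + 1.0, alpha) / std::pow(Again + 1.0 + it, alpha);
    for (R_xlen_t q = 0; q < 3 * n3; ++q) coef[q] += gain * grad[q] / gmax;
  }
  return List::create(_["coef"] = NumericVector(coef.begin(), coef.end()));
}
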