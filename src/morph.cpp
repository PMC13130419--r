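#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

static const int DX[6] = {1, -1, 0, 0, 0, 0};
static const int DY[6] = {0, 0, 1, -1, 0, 0};
static const int DZ[6] = {0, 0, 0, 0, 1, -1};

// Fill interior cavities of a 3D binary mask (6-connectivity): background
// voxels not reachable from the volume border become foreground.
// [[Rcpp::export(name = ".fill_holes3_cpp")]]
LogicalVector fill_holes3_cpp(LogicalVector mask) {
  IntegerVector d = mask.attr("dim");
  int nx = d[0], ny = d[1], nz = d[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<char> reach(n, 0);
  std::queue<R_xlen_t> q;
  auto idx = [&](int i, int j, int k) {
    return (R_xlen_t)i + (R_xlen_t)nx * ((R_xlen_t)j + (R_xlen_t)ny * k);
  };
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i)
        if (i == 0 || j == 0 || k == 0 || i == nx - 1 || j == ny - 1 || k == nz - 1) {
          R_xlen_t id = idx(i, j, k);
          if (!mask[id] && !reach[id]) { reach[id] = 1; q.push(id); }
        }
  while (!q.empty()) {
    R_xlen_t id = q.front(); q.pop();
    int k = (int)(id / ((R_xlen_t)nx * ny));
    int j = (int)((id / nx) % ny);
    int i = (int)(id % nx);
    for (int t = 0; t < 6; ++t) {
      int ii = i + DX[t], jj = j + DY[t], kk = k + DZ[t];
      if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
      R_xlen_t id2 = idx(ii, jj, kk);
      if (!mask[id2] && !reach[id2]) { reach[id2] = 1; q.push(id2); }
    }
  }
  LogicalVector out(n);
  out.attr("dim") = d;
  for (R_xlen_t id = 0; id < n; ++id) out[id] = mask[id] || !reach[id];
  return out;
}

// Number of 6-connected components of a binary mask.
// [[Rcpp::export(name = ".n_components3_cpp")]]
int n_components3_cpp(LogicalVector mask) {
  IntegerVector d = mask.attr("dim");
  int nx = d[0], ny = d[1], nz = d[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<char> seen(n, 0);
  std::queue<R_xlen_t> q;
  int ncomp = 0;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || seen[s]) continue;
    ncomp++;
    seen[s] = 1; q.push(s);
    while (!q.empty()) {
      R_xlen_t id = q.front(); q.pop();
      int k = (int)(id / ((R_xlen_t)nx * ny));
      int j = (int)((id / nx) % ny);
      int i = (int)(id % nx);
      for (int t = 0; t < 6; ++t) {
        int ii = i + DX[t], jj = j + DY[t], kk = k + DZ[t];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
        R_xlen_t id2 = (R_xlen_t)ii + (R_xlen_t)nx * ((R_xlen_t)jj + (R_xlen_t)ny * kk);
        if (mask[id2] && !seen[id2]) { seen[id2] = 1; q.push(id2); }
      }
    }
  }
  return ncomp;
}

// Boundary voxel centres (mm) of a binary mask: mask voxels with at least one
// 6-neighbour outside the mask or outside the volume.
static void boundary_points(const LogicalVector& mask, const NumericVector& spacing,
                            std::vector<double>& px, std::vector<double>& py,
                            std::vector<double>& pz) {
  IntegerVector d = mask.attr("dim");
  int nx = d[0], ny = d[1], nz = d[2];
  auto idx = [&](int i, int j, int k) {
    return (R_xlen_t)i + (R_xlen_t)nx * ((R_xlen_t)j + (R_xlen_t)ny * k);
  };
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        if (!mask[idx(i, j, k)]) continue;
        bool bnd = false;
        for (int t = 0; t < 6 && !bnd; ++t) {
          int ii = i + DX[t], jj = j + DY[t], kk = k + DZ[t];
          if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) bnd = true;
          else if (!mask[idx(ii, jj, kk)]) bnd = true;
        }
        if (bnd) {
          px.push_back(i * spacing[0]);
          py.push_back(j * spacing[1]);
          pz.push_back(k * spacing[2]);
        }
      }
}

// Symmetric Hausdorff distance (mm) between boundary voxel centres of two
// binary masks sharing a geometry.
// [[Rcpp::export(name = ".hausdorff_cpp")]]
double hausdorff_cpp(LogicalVector a, LogicalVector b, NumericVector spacing) {
  std::vector<double> ax, ay, az, bx, by, bz;
  boundary_points(a, spacing, ax, ay, az);
  boundary_points(b, spacing, bx, by, bz);
  if (ax.empty() || bx.empty()) stop("empty mask in hausdorff");
  double h = 0;
  for (int pass = 0; pass < 2; ++pass) {
    const std::vector<double>&sx = pass ? bx : ax, &sy = pass ? by : ay, &sz = pass ? bz : az;
    const std::vector<double>&tx = pass ? ax : bx, &ty = pass ? ay : by, &tz = pass ? az : bz;
    for (size_t i = 0; i < sx.size(); ++i) {
      double best = R_PosInf;
      for (size_t j = 0; j < tx.size(); ++j) {
        double dx = sx[i] - tx[j], dy = sy[i] - ty[j], dz = sz[i] - tz[j];
        double dd = dx * dx + dy * dy + dz * dz;
        if (dd < best) best = dd;
      }
      if (best > h) h = best;
    }
  }
  return std::sqrt(h);
}
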