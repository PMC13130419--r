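// 3D U-Net segmentation engine: im2col + BLAS convolutions (single precision),
// encoder-decoder with skip connections, per-channel sigmoid outputs trained
// with binary cross-entropy against one-hot targets, Adam optimiser, early
// stopping on validation loss. Whole-volume training, batch size 1. All large
// buffers (im2col patch matrices, activations) persist across optimisation
// steps to avoid allocation churn; the backward pass reuses each layer's
// patch matrix in place for its input-gradient scatter.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <random>
using namespace Rcpp;
using arma::fmat;
using arma::frowvec;

struct Dims {
  int nx, ny, nz;
  arma::uword n() const { return (arma::uword)nx * ny * nz; }
  Dims half() const { return Dims{nx / 2, ny / 2, nz / 2}; }
};

struct NetCfg {
  int levels, base, growth, in_ch, out_ch, k;
  int ch(int l) const { // encoder channels at level l; l = levels is bottleneck
    int c = base;
    for (int q = 0; q < l; ++q) c *= growth;
    return c;
  }
};

static NetCfg parse_cfg(List config) {
  NetCfg c;
  c.levels = as<int>(config["levels"]);
  c.base = as<int>(config["base_filters"]);
  c.growth = as<int>(config["growth"]);
  c.in_ch = as<int>(config["in_channels"]);
  c.out_ch = as<int>(config["out_channels"]);
  c.k = as<int>(config["kernel_size"]);
  if (c.levels < 1 || c.base < 1 || c.k % 2 != 1) stop("invalid U-Net config");
  if (c.in_ch != 1) stop("only single-channel (in-phase) input is supported");
  return c;
}

struct ConvShape { int cin, cout, k; };

// conv layers in execution order: per encoder level two convs, two bottleneck
// convs, per decoder level an up-convolution plus two post-concat convs, and
// a final 1x1x1 projection.
static std::vector<ConvShape> conv_shapes(const NetCfg& c) {
  std::vector<ConvShape> s;
  for (int l = 0; l < c.levels; ++l) {
    s.push_back({l == 0 ? c.in_ch : c.ch(l - 1), c.ch(l), c.k});
    s.push_back({c.ch(l), c.ch(l), c.k});
  }
  s.push_back({c.ch(c.levels - 1), c.ch(c.levels), c.k});
  s.push_back({c.ch(c.levels), c.ch(c.levels), c.k});
  for (int l = c.levels - 1; l >= 0; --l) {
    // up-projection: nearest-neighbour upsample followed by a 1x1x1
    // channel reduction (equivalent cost to a 2x2x2 transposed conv)
    s.push_back({l == c.levels - 1 ? c.ch(c.levels) : c.ch(l + 1), c.ch(l), 1});
    s.push_back({2 * c.ch(l), c.ch(l), c.k});
    s.push_back({c.ch(l), c.ch(l), c.k});
  }
  s.push_back({c.ch(0), c.out_ch, 1});
  return s;
}

// Deep-supervision heads: one 1x1x1 projection per decoder level 1..L-1
// (the coarse levels), used only during training. Loss weights halve per
// level and are normalised.
static int n_aux(const NetCfg& c) { return c.levels - 1; }

// [[Rcpp::export(name = ".unet_param_count_cpp")]]
double unet_param_count_cpp(List config) {
  NetCfg c = parse_cfg(config);
  double n = 0;
  for (const auto& s : conv_shapes(c))
    n += (double)s.cin * s.k * s.k * s.k * s.cout + s.cout;
  for (int l = 1; l <= n_aux(c); ++l)
    n += (double)(c.ch(l) + 1) * c.out_ch;
  return n;
}

// Patch extraction with zero padding k/2; P must not alias X. Only border
// entries are explicitly zeroed, interior runs are memcpy'd.
static void im2col(const fmat& X, Dims d, int k, fmat& P) {
  const int r = k / 2, k3 = k * k * k;
  const int Cin = X.n_cols, nx = d.nx, ny = d.ny, nz = d.nz;
  P.set_size(X.n_rows, (arma::uword)Cin * k3);
  for (int c = 0; c < Cin; ++c) {
    const float* src = X.colptr(c);
    int t = 0;
    for (int dz = -r; dz <= r; ++dz)
      for (int dy = -r; dy <= r; ++dy)
        for (int dx = -r; dx <= r; ++dx, ++t) {
          float* dst = P.colptr((arma::uword)c * k3 + t);
          for (int kz = 0; kz < nz; ++kz) {
            int z = kz + dz;
            if (z < 0 || z >= nz) {
              std::memset(dst + (size_t)nx * ((size_t)ny * kz), 0,
                          sizeof(float) * (size_t)nx * ny);
              continue;
            }
            for (int j = 0; j < ny; ++j) {
              int y = j + dy;
              size_t drow = (size_t)nx * (j + (size_t)ny * kz);
              if (y < 0 || y >= ny) {
                std::memset(dst + drow, 0, sizeof(float) * nx);
                continue;
              }
              int i0 = std::max(0, -dx), i1 = std::min(nx - 1, nx - 1 - dx);
              for (int i = 0; i < i0; ++i) dst[drow + i] = 0.0f;
              for (int i = i1 + 1; i < nx; ++i) dst[drow + i] = 0.0f;
              if (i1 >= i0) {
                size_t srow = (size_t)(i0 + dx) + (size_t)nx * (y + (size_t)ny * z);
                std::memcpy(dst + drow + i0, src + srow,
                            sizeof(float) * (i1 - i0 + 1));
              }
            }
          }
        }
  }
}

// Adjoint of im2col: scatter-add patch gradients back onto the input grid.
static void col2im(const fmat& dP, Dims d, int k, int Cin, fmat& dX) {
  const int r = k / 2, k3 = k * k * k;
  const int nx = d.nx, ny = d.ny, nz = d.nz;
  dX.zeros(dP.n_rows, Cin);
  for (int c = 0; c < Cin; ++c) {
    float* dst = dX.colptr(c);
    int t = 0;
    for (int dz = -r; dz <= r; ++dz)
      for (int dy = -r; dy <= r; ++dy)
        for (int dx = -r; dx <= r; ++dx, ++t) {
          const float* src = dP.colptr((arma::uword)c * k3 + t);
          for (int kz = 0; kz < nz; ++kz) {
            int z = kz + dz;
            if (z < 0 || z >= nz) continue;
            for (int j = 0; j < ny; ++j) {
              int y = j + dy;
              if (y < 0 || y >= ny) continue;
              int i0 = std::max(0, -dx), i1 = std::min(nx - 1, nx - 1 - dx);
              if (i1 < i0) continue;
              size_t prow = (size_t)i0 + (size_t)nx * (j + (size_t)ny * kz);
              size_t xrow = (size_t)(i0 + dx) + (size_t)nx * (y + (size_t)ny * z);
              const float* s = src + prow;
              float* o = dst + xrow;
              for (int i = 0; i <= i1 - i0; ++i) o[i] += s[i];
            }
          }
        }
  }
}

static void maxpool(const fmat& X, Dims d, fmat& Y, arma::umat& idx) {
  Dims h = d.half();
  Y.set_size(h.n(), X.n_cols);
  idx.set_size(h.n(), X.n_cols);
  for (arma::uword c = 0; c < X.n_cols; ++c) {
    const float* src = X.colptr(c);
    float* dst = Y.colptr(c);
    arma::uword* ix = idx.colptr(c);
    for (int k = 0; k < h.nz; ++k)
      for (int j = 0; j < h.ny; ++j)
        for (int i = 0; i < h.nx; ++i) {
          float best = -1e30f;
          size_t besti = 0;
          for (int dz = 0; dz < 2; ++dz)
            for (int dy = 0; dy < 2; ++dy)
              for (int dx = 0; dx < 2; ++dx) {
                size_t s = (size_t)(2 * i + dx) +
                           (size_t)d.nx * ((2 * j + dy) + (size_t)d.ny * (2 * k + dz));
                if (src[s] > best) { best = src[s]; besti = s; }
              }
          size_t o = (size_t)i + (size_t)h.nx * (j + (size_t)h.ny * k);
          dst[o] = best;
          ix[o] = besti;
        }
  }
}

static void maxpool_bwd(const fmat& dY, const arma::umat& idx, arma::uword n_in,
                        fmat& dX) {
  dX.zeros(n_in, dY.n_cols);
  for (arma::uword c = 0; c < dY.n_cols; ++c) {
    const float* g = dY.colptr(c);
    const arma::uword* ix = idx.colptr(c);
    float* o = dX.colptr(c);
    for (arma::uword r = 0; r < dY.n_rows; ++r) o[ix[r]] += g[r];
  }
}

static void upsample_nn(const fmat& X, Dims coarse, fmat& Y) {
  Dims f{coarse.nx * 2, coarse.ny * 2, coarse.nz * 2};
  Y.set_size(f.n(), X.n_cols);
  for (arma::uword c = 0; c < X.n_cols; ++c) {
    const float* src = X.colptr(c);
    float* dst = Y.colptr(c);
    for (int k = 0; k < f.nz; ++k)
      for (int j = 0; j < f.ny; ++j) {
        const float* srow = src + (size_t)coarse.nx * ((j / 2) + (size_t)coarse.ny * (k / 2));
        float* drow = dst + (size_t)f.nx * (j + (size_t)f.ny * k);
        for (int i = 0; i < f.nx; ++i) drow[i] = srow[i / 2];
      }
  }
}

static void upsample_nn_bwd(const fmat& dY, Dims coarse, fmat& dX) {
  Dims f{coarse.nx * 2, coarse.ny * 2, coarse.nz * 2};
  dX.zeros(coarse.n(), dY.n_cols);
  for (arma::uword c = 0; c < dY.n_cols; ++c) {
    const float* g = dY.colptr(c);
    float* o = dX.colptr(c);
    for (int k = 0; k < f.nz; ++k)
      for (int j = 0; j < f.ny; ++j) {
        float* orow = o + (size_t)coarse.nx * ((j / 2) + (size_t)coarse.ny * (k / 2));
        const float* grow = g + (size_t)f.nx * (j + (size_t)f.ny * k);
        for (int i = 0; i < f.nx; ++i) orow[i / 2] += grow[i];
      }
  }
}

struct Net {
  NetCfg cfg;
  std::vector<ConvShape> shapes;
  std::vector<fmat> W;
  std::vector<frowvec> b;
  std::vector<fmat> auxW;      // [l-1] for decoder level l = 1..levels-1
  std::vector<frowvec> auxb;
};

// Persistent workspace: per-conv patch matrix and post-activation output.
struct Cache {
  std::vector<fmat> conv_P;
  std::vector<fmat> conv_out;
  std::vector<arma::umat> pool_idx;
  std::vector<Dims> pool_in_dims;
  std::vector<fmat> pooled;
  std::vector<frowvec> norm_sd;  // per-channel instance-norm scale
  std::vector<fmat> aux_logits;  // [l-1], deep-supervision outputs
  std::vector<int> aux_src;      // conv index feeding each aux head
  fmat concat, up, logits;
  void init(size_t nconv, int levels) {
    conv_P.resize(nconv); conv_out.resize(nconv);
    pool_idx.resize(levels); pool_in_dims.resize(levels);
    pooled.resize(levels);
    norm_sd.resize(nconv);
    aux_logits.resize(std::max(levels - 1, 0));
    aux_src.assign(std::max(levels - 1, 0), -1);
  }
};

static const fmat& conv_forward(const Net& net, int li, const fmat& X, Dims d,
                                bool relu, Cache& cache) {
  fmat& P = cache.conv_P[li];
  if (net.shapes[li].k == 1) P = X;
  else im2col(X, d, net.shapes[li].k, P);
  fmat& Y = cache.conv_out[li];
  Y = P * net.W[li];
  Y.each_row() += net.b[li];
  if (relu) {
    // instance normalisation (affine-free, per channel over all voxels)
    // followed by leaky ReLU (slope 0.01); the standard conditioning for
    // whole-volume 3D U-Net training
    frowvec& sd = cache.norm_sd[li];
    sd.set_size(Y.n_cols);
    for (arma::uword c = 0; c < Y.n_cols; ++c) {
      float* y = Y.colptr(c);
      arma::uword n = Y.n_rows;
      double mu = 0;
      for (arma::uword r = 0; r < n; ++r) mu += y[r];
      mu /= n;
      double var = 0;
      for (arma::uword r = 0; r < n; ++r) {
        double d = y[r] - mu;
        var += d * d;
      }
      float s = (float)std::sqrt(var / n + 1e-5);
      sd[c] = s;
      float inv = 1.0f / s;
      for (arma::uword r = 0; r < n; ++r) {
        float v = (y[r] - (float)mu) * inv;
        y[r] = v > 0 ? v : 0.01f * v;
      }
    }
  }
  return Y;
}

// Forward pass; logits live in cache.logits. dims must divide by 2^levels.
static const fmat& forward(const Net& net, const fmat& input, Dims d0,
                           Cache& cache) {
  const NetCfg& c = net.cfg;
  int div = 1 << c.levels;
  if (d0.nx % div || d0.ny % div || d0.nz % div)
    stop("input grid %dx%dx%d is not divisible by 2^levels = %d; pad each axis to a multiple of %d",
         d0.nx, d0.ny, d0.nz, div, div);
  cache.init(net.shapes.size(), c.levels);
  Dims d = d0;
  int li = 0;
  const fmat* x = &input;
  for (int l = 0; l < c.levels; ++l) {
    x = &conv_forward(net, li, *x, d, true, cache); ++li;
    x = &conv_forward(net, li, *x, d, true, cache); ++li;
    maxpool(*x, d, cache.pooled[l], cache.pool_idx[l]);
    cache.pool_in_dims[l] = d;
    x = &cache.pooled[l];
    d = d.half();
  }
  x = &conv_forward(net, li, *x, d, true, cache); ++li;
  x = &conv_forward(net, li, *x, d, true, cache); ++li;
  for (int l = c.levels - 1; l >= 0; --l) {
    upsample_nn(*x, d, cache.up);
    d = Dims{d.nx * 2, d.ny * 2, d.nz * 2};
    x = &conv_forward(net, li, cache.up, d, true, cache); ++li;
    // skip connection: the pre-pool activation of encoder level l
    cache.concat = arma::join_rows(*x, cache.conv_out[2 * l + 1]);
    x = &conv_forward(net, li, cache.concat, d, true, cache); ++li;
    x = &conv_forward(net, li, *x, d, true, cache); ++li;
    if (l >= 1 && !net.auxW.empty()) {
      // deep-supervision head on the coarse decoder output
      fmat& az = cache.aux_logits[l - 1];
      az = (*x) * net.auxW[l - 1];
      az.each_row() += net.auxb[l - 1];
      cache.aux_src[l - 1] = li - 1;
    }
  }
  cache.logits = conv_forward(net, li, *x, d, false, cache);
  return cache.logits;
}

// BCE-with-logits loss vs one-hot targets from integer labels; fills dZ.
static double bce_logits(const fmat& Z, const int* lab, fmat* dZ) {
  arma::uword N = Z.n_rows, C = Z.n_cols;
  double denom = (double)N * C, loss = 0;
  if (dZ) dZ->set_size(N, C);
  for (arma::uword c = 0; c < C; ++c) {
    const float* z = Z.colptr(c);
    float* g = dZ ? dZ->colptr(c) : nullptr;
    for (arma::uword r = 0; r < N; ++r) {
      float t = (lab[r] == (int)c) ? 1.0f : 0.0f;
      float zv = z[r];
      loss += (zv > 0 ? zv : 0) - zv * t + std::log1p(std::exp(-std::fabs(zv)));
      if (g) {
        float sig = 1.0f / (1.0f + std::exp(-zv));
        g[r] = (float)((sig - t) / denom);
      }
    }
  }
  return loss / denom;
}

// apply ReLU mask, accumulate dW/db, and overwrite the cached patch matrix
// with the patch gradient (P is no longer needed once dW is formed)
static void conv_backward_core(const Net& net, Cache& cache, int li, fmat& dy,
                               bool relu, std::vector<fmat>& dW,
                               std::vector<frowvec>& db) {
  if (relu) {
    // backward through leaky ReLU then instance norm; the normalised
    // pre-activation is recovered from the (invertible) leaky output
    const fmat& out = cache.conv_out[li];
    const frowvec& sd = cache.norm_sd[li];
    arma::uword n = dy.n_rows;
    for (arma::uword c = 0; c < dy.n_cols; ++c) {
      const float* o = out.colptr(c);
      float* g = dy.colptr(c);
      double sum_g = 0, sum_gx = 0;
      for (arma::uword r = 0; r < n; ++r) {
        float xh = o[r] > 0 ? o[r] : o[r] * 100.0f;  // invert leaky slope
        if (o[r] <= 0) g[r] *= 0.01f;
        sum_g += g[r];
        sum_gx += (double)g[r] * xh;
      }
      float mg = (float)(sum_g / n), mgx = (float)(sum_gx / n);
      float inv = 1.0f / sd[c];
      for (arma::uword r = 0; r < n; ++r) {
        float xh = o[r] > 0 ? o[r] : o[r] * 100.0f;
        g[r] = inv * (g[r] - mg - xh * mgx);
      }
    }
  }
  dW[li] = cache.conv_P[li].t() * dy;
  db[li] = arma::sum(dy, 0);
  cache.conv_P[li] = dy * net.W[li].t();  // now holds dP
}

// dAux may be empty (no deep supervision) or hold one scaled gradient per
// coarse decoder level; dWaux/dbaux are filled alongside.
static void backward(const Net& net, Cache& cache, fmat& dLogits,
                     std::vector<fmat>& dAux, Dims d0,
                     std::vector<fmat>& dW, std::vector<frowvec>& db,
                     std::vector<fmat>& dWaux, std::vector<frowvec>& dbaux) {
  const NetCfg& c = net.cfg;
  size_t nc = net.shapes.size();
  int li = (int)nc - 1;
  fmat dx;
  // final 1x1 conv (no relu): patch matrix is the input itself
  dW[li] = cache.conv_P[li].t() * dLogits;
  db[li] = arma::sum(dLogits, 0);
  dx = dLogits * net.W[li].t();
  --li;
  std::vector<Dims> level_dims(c.levels + 1);
  level_dims[0] = d0;
  for (int l = 1; l <= c.levels; ++l) level_dims[l] = level_dims[l - 1].half();
  std::vector<fmat> dskip(c.levels);
  for (int l = 0; l < c.levels; ++l) {  // decoder, finest level first
    Dims d = level_dims[l];
    for (int rep = 0; rep < 2; ++rep) {
      conv_backward_core(net, cache, li, dx, true, dW, db);
      col2im(cache.conv_P[li], d, net.shapes[li].k, net.shapes[li].cin, dx);
      --li;
    }
    int cu = net.shapes[li].cout;
    fmat dup = dx.cols(0, cu - 1);
    dskip[l] = dx.cols(cu, dx.n_cols - 1);
    conv_backward_core(net, cache, li, dup, true, dW, db);
    fmat dUpIn;
    col2im(cache.conv_P[li], d, net.shapes[li].k, net.shapes[li].cin, dUpIn);
    upsample_nn_bwd(dUpIn, level_dims[l + 1], dx);
    --li;
    // inject the deep-supervision gradient of the next (coarser) level
    int lvl = l + 1;
    if (lvl <= c.levels - 1 && !dAux.empty() && dAux[lvl - 1].n_elem > 0) {
      const fmat& ain = cache.conv_out[cache.aux_src[lvl - 1]];
      dWaux[lvl - 1] = ain.t() * dAux[lvl - 1];
      dbaux[lvl - 1] = arma::sum(dAux[lvl - 1], 0);
      dx += dAux[lvl - 1] * net.auxW[lvl - 1].t();
    }
  }
  for (int rep = 0; rep < 2; ++rep) {  // bottleneck
    Dims d = level_dims[c.levels];
    conv_backward_core(net, cache, li, dx, true, dW, db);
    col2im(cache.conv_P[li], d, net.shapes[li].k, net.shapes[li].cin, dx);
    --li;
  }
  for (int l = c.levels - 1; l >= 0; --l) {  // encoder, deepest first
    fmat dpool;
    maxpool_bwd(dx, cache.pool_idx[l], cache.pool_in_dims[l].n(), dpool);
    dx = dpool + dskip[l];
    Dims d = level_dims[l];
    for (int rep = 0; rep < 2; ++rep) {
      conv_backward_core(net, cache, li, dx, true, dW, db);
      col2im(cache.conv_P[li], d, net.shapes[li].k, net.shapes[li].cin, dx);
      --li;
    }
  }
}

static Net net_from_r(List weights, List biases, List aux_weights,
                      List aux_biases, List config) {
  Net net;
  net.cfg = parse_cfg(config);
  net.shapes = conv_shapes(net.cfg);
  size_t nc = net.shapes.size();
  if ((size_t)weights.size() != nc) stop("weight list does not match architecture");
  net.W.resize(nc); net.b.resize(nc);
  for (size_t i = 0; i < nc; ++i) {
    NumericMatrix w = weights[i];
    NumericVector bv = biases[i];
    net.W[i] = arma::conv_to<fmat>::from(as<arma::mat>(w));
    net.b[i] = arma::conv_to<frowvec>::from(as<arma::rowvec>(bv));
  }
  int na = n_aux(net.cfg);
  if (aux_weights.size() == na) {
    net.auxW.resize(na); net.auxb.resize(na);
    for (int i = 0; i < na; ++i) {
      NumericMatrix w = aux_weights[i];
      NumericVector bv = aux_biases[i];
      net.auxW[i] = arma::conv_to<fmat>::from(as<arma::mat>(w));
      net.auxb[i] = arma::conv_to<frowvec>::from(as<arma::rowvec>(bv));
    }
  }
  return net;
}

static List net_to_r(const Net& net) {
  List W(net.W.size()), B(net.b.size());
  for (size_t i = 0; i < net.W.size(); ++i) {
    W[i] = wrap(arma::conv_to<arma::mat>::from(net.W[i]));
    B[i] = wrap(arma::conv_to<arma::rowvec>::from(net.b[i]));
  }
  List AW(net.auxW.size()), AB(net.auxb.size());
  for (size_t i = 0; i < net.auxW.size(); ++i) {
    AW[i] = wrap(arma::conv_to<arma::mat>::from(net.auxW[i]));
    AB[i] = wrap(arma::conv_to<arma::rowvec>::from(net.auxb[i]));
  }
  return List::create(_["weights"] = W, _["biases"] = B,
                      _["aux_weights"] = AW, _["aux_biases"] = AB);
}

// He-normal initialisation, deterministic under seed.
// [[Rcpp::export(name = ".unet_init_cpp")]]
List unet_init_cpp(List config, int seed) {
  NetCfg c = parse_cfg(config);
  auto shapes = conv_shapes(c);
  std::mt19937 rng(seed);
  std::normal_distribution<float> nd(0.0f, 1.0f);
  List W(shapes.size()), B(shapes.size());
  for (size_t i = 0; i < shapes.size(); ++i) {
    int fan_in = shapes[i].cin * shapes[i].k * shapes[i].k * shapes[i].k;
    float sd = std::sqrt(2.0f / fan_in);
    arma::mat w(fan_in, shapes[i].cout);
    for (arma::uword q = 0; q < w.n_elem; ++q) w[q] = sd * nd(rng);
    W[i] = wrap(w);
    NumericVector bias(shapes[i].cout, 0.0);
    if (i == shapes.size() - 1) {
      // prior-informed output bias: segmentation foreground is sparse, so
      // start with the background channel confident and foreground channels
      // suppressed; training then focuses on discrimination from step one
      bias[0] = 2.0;
      for (int q = 1; q < shapes[i].cout; ++q) bias[q] = -2.0;
    }
    B[i] = bias;
  }
  int na = n_aux(c);
  List AW(na), AB(na);
  for (int l = 1; l <= na; ++l) {
    int cin = c.ch(l);
    float sd = std::sqrt(2.0f / cin);
    arma::mat w(cin, c.out_ch);
    for (arma::uword q = 0; q < w.n_elem; ++q) w[q] = sd * nd(rng);
    AW[l - 1] = wrap(w);
    NumericVector bias(c.out_ch, -2.0);
    bias[0] = 2.0;
    AB[l - 1] = bias;
  }
  return List::create(_["weights"] = W, _["biases"] = B,
                      _["aux_weights"] = AW, _["aux_biases"] = AB,
                      _["n_params"] = unet_param_count_cpp(config));
}

// stride-downsampled label targets for the deep-supervision heads
static void build_targets(const std::vector<int>& lab0, Dims d0, int levels,
                          std::vector<std::vector<int>>& out) {
  int na = std::max(levels - 1, 0);
  out.resize(na + 1);
  out[0] = lab0;
  for (int l = 1; l <= na; ++l) {
    int f = 1 << l;
    Dims d{d0.nx / f, d0.ny / f, d0.nz / f};
    out[l].resize(d.n());
    for (int k = 0; k < d.nz; ++k)
      for (int j = 0; j < d.ny; ++j)
        for (int i = 0; i < d.nx; ++i)
          out[l][(size_t)i + (size_t)d.nx * (j + (size_t)d.ny * k)] =
              lab0[(size_t)i * f +
                   (size_t)d0.nx * ((size_t)j * f + (size_t)d0.ny * ((size_t)k * f))];
  }
}

// multi-scale loss: the full-resolution output and every coarse head are
// weighted equally (normalised to sum 1). Equal weighting keeps a strong
// pull from the coarse heads, whose far better foreground/background
// balance lets them discover structures first and feed the shared trunk.
static double ds_loss(const Net& net, Cache& cache,
                      const std::vector<std::vector<int>>& tgt,
                      fmat* dZ, std::vector<fmat>* dAux) {
  int na = (int)net.auxW.size();
  double w = 1.0 / (na + 1);
  double total = w * bce_logits(cache.logits, tgt[0].data(), dZ);
  if (dZ) *dZ *= (float)w;
  if (dAux) dAux->assign(na, fmat());
  for (int l = 1; l <= na; ++l) {
    fmat* g = dAux ? &(*dAux)[l - 1] : nullptr;
    total += w * bce_logits(cache.aux_logits[l - 1], tgt[l].data(), g);
    if (g) *g *= (float)w;
  }
  return total;
}

static fmat volume_to_fmat(NumericVector arr, Dims& d) {
  IntegerVector dim = arr.attr("dim");
  d = Dims{dim[0], dim[1], dim[2]};
  fmat x(d.n(), 1);
  const double* v = arr.begin();
  float* o = x.colptr(0);
  for (arma::uword i = 0; i < d.n(); ++i) o[i] = (float)v[i];
  return x;
}

// Train with Adam; returns updated weights, per-epoch history, best epoch.
// [[Rcpp::export(name = ".unet_train_cpp")]]
List unet_train_cpp(List weights, List biases, List aux_weights,
                    List aux_biases, List config,
                    List train_x, List train_y, List val_x, List val_y,
                    int max_epochs, int patience, double lr, int seed) {
  Net net = net_from_r(weights, biases, aux_weights, aux_biases, config);
  size_t nc = net.shapes.size();
  size_t na = net.auxW.size();
  std::vector<fmat> mW(nc), vW(nc), dW(nc);
  std::vector<frowvec> mb(nc), vb(nc), db(nc);
  std::vector<fmat> mAW(na), vAW(na), dWaux(na);
  std::vector<frowvec> mab(na), vab(na), dbaux(na);
  for (size_t i = 0; i < nc; ++i) {
    mW[i].zeros(net.W[i].n_rows, net.W[i].n_cols);
    vW[i].zeros(net.W[i].n_rows, net.W[i].n_cols);
    mb[i].zeros(net.b[i].n_elem);
    vb[i].zeros(net.b[i].n_elem);
  }
  for (size_t i = 0; i < na; ++i) {
    mAW[i].zeros(net.auxW[i].n_rows, net.auxW[i].n_cols);
    vAW[i].zeros(net.auxW[i].n_rows, net.auxW[i].n_cols);
    mab[i].zeros(net.auxb[i].n_elem);
    vab[i].zeros(net.auxb[i].n_elem);
  }
  int ntr = train_x.size(), nval = val_x.size();
  std::vector<fmat> TX(ntr), VX(nval);
  std::vector<std::vector<std::vector<int>>> TY(ntr), VY(nval);
  Dims d0{0, 0, 0};
  for (int i = 0; i < ntr; ++i) {
    Dims d;
    TX[i] = volume_to_fmat(train_x[i], d);
    if (i == 0) d0 = d;
    else if (d.nx != d0.nx || d.ny != d0.ny || d.nz != d0.nz)
      stop("training volumes differ in shape");
    IntegerVector y = train_y[i];
    std::vector<int> flat(y.begin(), y.end());
    build_targets(flat, d, net.cfg.levels, TY[i]);
  }
  for (int i = 0; i < nval; ++i) {
    Dims d;
    VX[i] = volume_to_fmat(val_x[i], d);
    if (d.nx != d0.nx || d.ny != d0.ny || d.nz != d0.nz)
      stop("validation volume shape mismatch");
    IntegerVector y = val_y[i];
    std::vector<int> flat(y.begin(), y.end());
    build_targets(flat, d, net.cfg.levels, VY[i]);
  }
  std::mt19937 rng(seed);
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long tstep = 0;
  std::vector<double> train_hist, val_hist;
  double best_val = R_PosInf;
  int best_epoch = -1;
  std::vector<fmat> bestW, bestAW;
  std::vector<frowvec> bestb, bestab;
  bool stopped_early = false;
  std::vector<int> order(ntr);
  for (int i = 0; i < ntr; ++i) order[i] = i;
  Cache cache;
  fmat dZ;
  std::vector<fmat> dAux;
  auto adam = [&](fmat& p, fmat& m, fmat& v, const fmat& g,
                  double eff_lr, double bc1, double bc2) {
    m = (float)b1 * m + (float)(1 - b1) * g;
    v = (float)b2 * v + (float)(1 - b2) * (g % g);
    p -= (float)(eff_lr / bc1) * m / (arma::sqrt(v / (float)bc2) + (float)eps);
  };
  auto adam_v = [&](frowvec& p, frowvec& m, frowvec& v, const frowvec& g,
                    double eff_lr, double bc1, double bc2) {
    m = (float)b1 * m + (float)(1 - b1) * g;
    v = (float)b2 * v + (float)(1 - b2) * (g % g);
    p -= (float)(eff_lr / bc1) * m / (arma::sqrt(v / (float)bc2) + (float)eps);
  };
  for (int epoch = 0; epoch < max_epochs; ++epoch) {
    std::shuffle(order.begin(), order.end(), rng);
    double tl = 0;
    for (int oi = 0; oi < ntr; ++oi) {
      int i = order[oi];
      forward(net, TX[i], d0, cache);
      tl += ds_loss(net, cache, TY[i], &dZ, &dAux);
      backward(net, cache, dZ, dAux, d0, dW, db, dWaux, dbaux);
      ++tstep;
      // linear warm-up: early steps are fragile (second-moment estimates
      // still uninformative), so ramp the step size over the first 30 steps
      double eff_lr = lr * std::min(1.0, (double)tstep / 30.0);
      double bc1 = 1.0 - std::pow(b1, (double)tstep);
      double bc2 = 1.0 - std::pow(b2, (double)tstep);
      for (size_t q = 0; q < nc; ++q) {
        adam(net.W[q], mW[q], vW[q], dW[q], eff_lr, bc1, bc2);
        adam_v(net.b[q], mb[q], vb[q], db[q], eff_lr, bc1, bc2);
      }
      for (size_t q = 0; q < na; ++q) {
        if (dWaux[q].n_elem == 0) continue;
        adam(net.auxW[q], mAW[q], vAW[q], dWaux[q], eff_lr, bc1, bc2);
        adam_v(net.auxb[q], mab[q], vab[q], dbaux[q], eff_lr, bc1, bc2);
      }
    }
    train_hist.push_back(tl / std::max(1, ntr));
    double vl = 0;
    for (int i = 0; i < nval; ++i) {
      forward(net, VX[i], d0, cache);
      vl += ds_loss(net, cache, VY[i], nullptr, nullptr);
    }
    vl /= std::max(1, nval);
    val_hist.push_back(vl);
    if (nval > 0 && vl < best_val) {
      best_val = vl;
      best_epoch = epoch;
      bestW = net.W;
      bestb = net.b;
      bestAW = net.auxW;
      bestab = net.auxb;
    } else if (nval > 0 && patience > 0 && epoch - best_epoch >= patience) {
      stopped_early = true;
      break;
    }
    Rcpp::checkUserInterrupt();
  }
  if (best_epoch >= 0) {
    net.W = bestW; net.b = bestb;
    net.auxW = bestAW; net.auxb = bestab;
  }
  List out = net_to_r(net);
  out["train_loss"] = NumericVector(train_hist.begin(), train_hist.end());
  out["val_loss"] = NumericVector(val_hist.begin(), val_hist.end());
  out["best_epoch"] = best_epoch + 1; // 1-based for R
  out["stopped_early"] = stopped_early;
  return out;
}

// Predict integer labels (argmax over sigmoid channels; ties -> lowest
// channel, i.e. background first).
// [[Rcpp::export(name = ".unet_predict_cpp")]]
IntegerVector unet_predict_cpp(List weights, List biases, List config,
                               NumericVector vol) {
  Net net = net_from_r(weights, biases, List(), List(), config);
  Dims d;
  fmat x = volume_to_fmat(vol, d);
  Cache cache;
  const fmat& logits = forward(net, x, d, cache);
  IntegerVector out(x.n_rows);
  out.attr("dim") = vol.attr("dim");
  for (arma::uword r = 0; r < logits.n_rows; ++r) {
    int best = 0;
    float bv = logits(r, 0);
    for (arma::uword c = 1; c < logits.n_cols; ++c)
      if (logits(r, c) > bv) { bv = logits(r, c); best = (int)c; }
    out[r] = best;
  }
  return out;
}

// Loss and analytic parameter gradients for one example (gradient-check
// oracle hook used by the test suite).
// [[Rcpp::export(name = ".unet_lossgrad_cpp")]]
List unet_lossgrad_cpp(List weights, List biases, List aux_weights,
                       List aux_biases, List config,
                       NumericVector vol, IntegerVector lab,
                       bool want_grad) {
  Net net = net_from_r(weights, biases, aux_weights, aux_biases, config);
  Dims d;
  fmat x = volume_to_fmat(vol, d);
  Cache cache;
  forward(net, x, d, cache);
  std::vector<int> flat(lab.begin(), lab.end());
  std::vector<std::vector<int>> tgt;
  build_targets(flat, d, net.cfg.levels, tgt);
  if (!want_grad) {
    double loss = ds_loss(net, cache, tgt, nullptr, nullptr);
    return List::create(_["loss"] = loss);
  }
  fmat dZ;
  std::vector<fmat> dAux;
  double loss = ds_loss(net, cache, tgt, &dZ, &dAux);
  std::vector<fmat> dW(net.shapes.size()), dWaux(net.auxW.size());
  std::vector<frowvec> db(net.shapes.size()), dbaux(net.auxW.size());
  backward(net, cache, dZ, dAux, d, dW, db, dWaux, dbaux);
  List gW(dW.size()), gb(db.size()), gAW(dWaux.size()), gab(dbaux.size());
  for (size_t i = 0; i < dW.size(); ++i) {
    gW[i] = wrap(arma::conv_to<arma::mat>::from(dW[i]));
    gb[i] = wrap(arma::conv_to<arma::rowvec>::from(db[i]));
  }
  for (size_t i = 0; i < dWaux.size(); ++i) {
    gAW[i] = wrap(arma::conv_to<arma::mat>::from(dWaux[i]));
    gab[i] = wrap(arma::conv_to<arma::rowvec>::from(dbaux[i]));
  }
  return List::create(_["loss"] = loss, _["grad_weights"] = gW,
                      _["grad_biases"] = gb, _["grad_aux_weights"] = gAW,
                      _["grad_aux_biases"] = gab);
}
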