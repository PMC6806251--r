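// Compact convolutional classifier over pose-evolution maps.
//
// Architecture: two blocks of two 3x3 convolutions (block widths w1, w2;
// first layer of each block stride 2, second stride 1, "same" padding),
// each convolution followed by ReLU, batch normalization and dropout;
// then global average pooling and a fully connected softmax layer.
// Trained with Adam on softmax cross-entropy. Single precision
// throughout so the convolutions (lowered to GEMM via im2col) run on
// BLAS sgemm. All per-batch buffers are allocated once and reused
// across batches, and the ReLU/batch-norm/dropout stages are fused
// column-wise loops, so the non-GEMM cost stays memory-bound.
//
// Feature-map memory layout: fmat (channels x H*W*batch), where the
// column index is (h + H*w) + H*W*b. A flattened R map array of dim
// (channels, H, W) reinterprets to this layout with no copy.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <random>
#include <vector>
#include <cstring>

using namespace Rcpp;
using arma::fmat;
using arma::fvec;

static const float BN_EPS = 1e-5f;
static const float BN_MOMENTUM = 0.9f;

// xorshift64* : cheap deterministic RNG for dropout masks
struct FastRng {
  uint64_t s;
  explicit FastRng(uint64_t seed) : s(seed ? seed : 0x9e3779b97f4a7c15ULL) {}
  inline float unif() {
    s ^= s >> 12; s ^= s << 25; s ^= s >> 27;
    uint64_t r = s * 0x2545F4914F6CDD1DULL;
    return (float)((r >> 40) * (1.0 / 16777216.0));
  }
};

struct ConvSpec {
  int Cin, Cout, stride;
  int Hin, Win, Hout, Wout, padT, padL;
};

static void same_pad(int in, int s, int &out, int &pad_beg) {
  out = (in + s - 1) / s;
  int total = std::max(0, (out - 1) * s + 3 - in);
  pad_beg = total / 2;
}

static std::vector<ConvSpec> make_specs(int Cin, int H, int W,
                                        int w1, int w2) {
  int Couts[4] = {w1, w1, w2, w2};
  int strides[4] = {2, 1, 2, 1};
  std::vector<ConvSpec> specs(4);
  int h = H, w = W, cin = Cin;
  for (int l = 0; l < 4; ++l) {
    ConvSpec &s = specs[l];
    s.Cin = cin; s.Cout = Couts[l]; s.stride = strides[l];
    s.Hin = h; s.Win = w;
    same_pad(h, s.stride, s.Hout, s.padT);
    same_pad(w, s.stride, s.Wout, s.padL);
    h = s.Hout; w = s.Wout; cin = s.Cout;
  }
  return specs;
}

// col row layout: (kh + 3*kw)*Cin + c  -> channels contiguous per tap.
// Writes only in-bounds taps; the caller keeps padding rows zeroed
// (they are the same cells for every batch, so zero-filling the buffer
// once at allocation suffices).
static void im2col(const fmat &X, const ConvSpec &s, int B, fmat &col) {
  const int P = s.Hout * s.Wout;
  const float *xp = X.memptr();
  float *cp = col.memptr();
  const size_t xcol = s.Cin;
  const size_t ccol = 9 * (size_t)s.Cin;
  for (int b = 0; b < B; ++b) {
    const size_t xoff = (size_t)b * s.Hin * s.Win;
    for (int wo = 0; wo < s.Wout; ++wo) {
      for (int kw = 0; kw < 3; ++kw) {
        int win = wo * s.stride - s.padL + kw;
        if (win < 0 || win >= s.Win) continue;
        for (int ho = 0; ho < s.Hout; ++ho) {
          int hin = ho * s.stride - s.padT;
          size_t cc = ((size_t)(ho + s.Hout * wo) + (size_t)b * P) * ccol;
          for (int kh = 0; kh < 3; ++kh) {
            int h = hin + kh;
            if (h < 0 || h >= s.Hin) continue;
            std::memcpy(cp + cc + (size_t)(kh + 3 * kw) * s.Cin,
                        xp + (xoff + (size_t)(h + s.Hin * win)) * xcol,
                        xcol * sizeof(float));
          }
        }
      }
    }
  }
}

static void col2im_add(const fmat &dcol, const ConvSpec &s, int B,
                       fmat &dX) {
  const int P = s.Hout * s.Wout;
  const float *cp = dcol.memptr();
  float *xp = dX.memptr();
  const size_t xcol = s.Cin;
  const size_t ccol = 9 * (size_t)s.Cin;
  for (int b = 0; b < B; ++b) {
    const size_t xoff = (size_t)b * s.Hin * s.Win;
    for (int wo = 0; wo < s.Wout; ++wo) {
      for (int kw = 0; kw < 3; ++kw) {
        int win = wo * s.stride - s.padL + kw;
        if (win < 0 || win >= s.Win) continue;
        for (int ho = 0; ho < s.Hout; ++ho) {
          int hin = ho * s.stride - s.padT;
          size_t cc = ((size_t)(ho + s.Hout * wo) + (size_t)b * P) * ccol;
          for (int kh = 0; kh < 3; ++kh) {
            int h = hin + kh;
            if (h < 0 || h >= s.Hin) continue;
            const float *src = cp + cc + (size_t)(kh + 3 * kw) * s.Cin;
            float *dst = xp + (xoff + (size_t)(h + s.Hin * win)) * xcol;
            for (size_t c = 0; c < xcol; ++c) dst[c] += src[c];
          }
        }
      }
    }
  }
}

struct Params {
  std::vector<fmat> W;
  std::vector<fvec> b;
  std::vector<fvec> gamma, beta, rmean, rvar;
};

static Params params_from_list(List lst) {
  Params p;
  for (int l = 0; l < 5; ++l) {
    std::string i = std::to_string(l + 1);
    p.W.push_back(arma::conv_to<fmat>::from(
        as<arma::mat>((NumericMatrix)lst["W" + i])));
    p.b.push_back(arma::conv_to<fvec>::from(
        as<arma::vec>((NumericVector)lst["b" + i])));
  }
  for (int l = 0; l < 4; ++l) {
    std::string i = std::to_string(l + 1);
    p.gamma.push_back(arma::conv_to<fvec>::from(
        as<arma::vec>((NumericVector)lst["gamma" + i])));
    p.beta.push_back(arma::conv_to<fvec>::from(
        as<arma::vec>((NumericVector)lst["beta" + i])));
    p.rmean.push_back(arma::conv_to<fvec>::from(
        as<arma::vec>((NumericVector)lst["rmean" + i])));
    p.rvar.push_back(arma::conv_to<fvec>::from(
        as<arma::vec>((NumericVector)lst["rvar" + i])));
  }
  return p;
}

static List params_to_list(const Params &p) {
  List lst;
  for (int l = 0; l < 5; ++l) {
    std::string i = std::to_string(l + 1);
    lst["W" + i] = wrap(arma::conv_to<arma::mat>::from(p.W[l]));
    lst["b" + i] = wrap(arma::conv_to<arma::vec>::from(p.b[l]));
  }
  for (int l = 0; l < 4; ++l) {
    std::string i = std::to_string(l + 1);
    lst["gamma" + i] = wrap(arma::conv_to<arma::vec>::from(p.gamma[l]));
    lst["beta" + i] = wrap(arma::conv_to<arma::vec>::from(p.beta[l]));
    lst["rmean" + i] = wrap(arma::conv_to<arma::vec>::from(p.rmean[l]));
    lst["rvar" + i] = wrap(arma::conv_to<arma::vec>::from(p.rvar[l]));
  }
  return lst;
}

// [[Rcpp::export(name = ".cnn_init")]]
List cnn_init(IntegerVector dims, IntegerVector widths, int n_classes,
              int seed) {
  int Cin = dims[0], H = dims[1], W = dims[2];
  std::vector<ConvSpec> specs = make_specs(Cin, H, W, widths[0], widths[1]);
  std::mt19937 rng((unsigned)seed);
  std::normal_distribution<float> nd(0.0f, 1.0f);
  Params p;
  for (int l = 0; l < 4; ++l) {
    const ConvSpec &s = specs[l];
    float sd = std::sqrt(2.0f / (9.0f * s.Cin));
    fmat Wl(s.Cout, 9 * s.Cin);
    for (arma::uword i = 0; i < Wl.n_elem; ++i) Wl[i] = sd * nd(rng);
    p.W.push_back(Wl);
    p.b.push_back(fvec(s.Cout, arma::fill::zeros));
    p.gamma.push_back(fvec(s.Cout, arma::fill::ones));
    p.beta.push_back(fvec(s.Cout, arma::fill::zeros));
    p.rmean.push_back(fvec(s.Cout, arma::fill::zeros));
    p.rvar.push_back(fvec(s.Cout, arma::fill::ones));
  }
  int K = widths[1];
  float sd = std::sqrt(2.0f / K);
  fmat Wfc(n_classes, K);
  for (arma::uword i = 0; i < Wfc.n_elem; ++i) Wfc[i] = sd * nd(rng);
  p.W.push_back(Wfc);
  p.b.push_back(fvec(n_classes, arma::fill::zeros));
  return params_to_list(p);
}

// per-batch reusable buffers for one layer
struct LayerBuf {
  fmat col, Z, xhat, out, mask, dZ, dcol;
  fvec invstd;
};

struct Workspace {
  int B = 0;
  fmat Xb;                    // gathered input columns (D x B)
  std::vector<LayerBuf> lb;   // 4 layers
  std::vector<fmat> dX;       // grad wrt input of layers 1..3 (index l-1)
  fmat dcur4, feat, dfeat;
  void init(int B_, int D, const std::vector<ConvSpec> &specs,
            bool need_mask) {
    B = B_;
    Xb.set_size(D, B);
    lb.resize(4);
    dX.resize(3);
    for (int l = 0; l < 4; ++l) {
      const ConvSpec &s = specs[l];
      arma::uword n = (arma::uword)s.Hout * s.Wout * B;
      lb[l].col.zeros(9 * s.Cin, n);  // padding rows stay zero
      lb[l].Z.set_size(s.Cout, n);
      lb[l].xhat.set_size(s.Cout, n);
      lb[l].out.set_size(s.Cout, n);
      if (need_mask) lb[l].mask.set_size(s.Cout, n);
      lb[l].dZ.set_size(s.Cout, n);
      if (l > 0) {
        lb[l].dcol.set_size(9 * s.Cin, n);
        dX[l - 1].set_size(s.Cin,
                           (arma::uword)s.Hin * s.Win * B);
      }
    }
    const ConvSpec &last = specs[3];
    dcur4.set_size(last.Cout, (arma::uword)last.Hout * last.Wout * B);
    feat.set_size(last.Cout, B);
    dfeat.set_size(last.Cout, B);
  }
};

// fused ReLU -> batch norm -> dropout (training mode), column-wise so
// the channel loops vectorize
static void block_forward_train(Params &p, int l, float dropout,
                                FastRng &rng, LayerBuf &c, bool first) {
  const int C = (int)c.Z.n_rows;
  const size_t Ncol = c.Z.n_cols;
  const float *z = c.Z.memptr();
  std::vector<double> sum(C, 0.0), sumsq(C, 0.0);
  for (size_t j = 0; j < Ncol; ++j) {
    const float *zc = z + j * C;
    for (int ch = 0; ch < C; ++ch) {
      float a = zc[ch] > 0.0f ? zc[ch] : 0.0f;
      sum[ch] += a; sumsq[ch] += (double)a * a;
    }
  }
  fvec mu(C), var(C);
  c.invstd.set_size(C);
  for (int ch = 0; ch < C; ++ch) {
    mu[ch] = (float)(sum[ch] / Ncol);
    double v = sumsq[ch] / Ncol - (double)mu[ch] * mu[ch];
    var[ch] = (float)std::max(v, 0.0);
    c.invstd[ch] = 1.0f / std::sqrt(var[ch] + BN_EPS);
  }
  if (first) {
    // seed the running statistics from the first batch so eval-mode
    // forward passes are sane from the first epoch
    p.rmean[l] = mu;
    p.rvar[l] = var;
  } else {
    p.rmean[l] = BN_MOMENTUM * p.rmean[l] + (1 - BN_MOMENTUM) * mu;
    p.rvar[l] = BN_MOMENTUM * p.rvar[l] + (1 - BN_MOMENTUM) * var;
  }

  float *xh = c.xhat.memptr();
  float *out = c.out.memptr();
  const float *gam = p.gamma[l].memptr();
  const float *bet = p.beta[l].memptr();
  const float *muv = mu.memptr();
  const float *isv = c.invstd.memptr();
  if (dropout > 0.0f) {
    float *mk = c.mask.memptr();
    const float scale = 1.0f / (1.0f - dropout);
    for (size_t j = 0; j < Ncol; ++j) {
      const size_t o = j * C;
      const float *zc = z + o;
      for (int ch = 0; ch < C; ++ch) {
        float a = zc[ch] > 0.0f ? zc[ch] : 0.0f;
        float x = (a - muv[ch]) * isv[ch];
        xh[o + ch] = x;
        float m = (rng.unif() < dropout) ? 0.0f : scale;
        mk[o + ch] = m;
        out[o + ch] = (gam[ch] * x + bet[ch]) * m;
      }
    }
  } else {
    for (size_t j = 0; j < Ncol; ++j) {
      const size_t o = j * C;
      const float *zc = z + o;
      for (int ch = 0; ch < C; ++ch) {
        float a = zc[ch] > 0.0f ? zc[ch] : 0.0f;
        float x = (a - muv[ch]) * isv[ch];
        xh[o + ch] = x;
        out[o + ch] = gam[ch] * x + bet[ch];
      }
    }
  }
}

// fused backward through dropout -> batch norm -> ReLU; consumes dout
// in place and fills c.dZ; also accumulates dgamma/dbeta/db
static void block_backward(fmat &dout, const Params &p, int l,
                           LayerBuf &c, fvec &dgamma, fvec &dbeta,
                           fvec &db) {
  const int C = (int)dout.n_rows;
  const size_t Ncol = dout.n_cols;
  float *do_ = dout.memptr();
  const float *xh = c.xhat.memptr();
  const float *mk = c.mask.n_elem ? c.mask.memptr() : nullptr;
  const float *gam = p.gamma[l].memptr();
  const float *isv = c.invstd.memptr();
  const float *z = c.Z.memptr();
  std::vector<double> dg(C, 0.0), dbt(C, 0.0), sdx(C, 0.0), sdxx(C, 0.0);
  for (size_t j = 0; j < Ncol; ++j) {
    const size_t o = j * C;
    for (int ch = 0; ch < C; ++ch) {
      float d = mk ? do_[o + ch] * mk[o + ch] : do_[o + ch];
      do_[o + ch] = d;
      dg[ch] += (double)d * xh[o + ch];
      dbt[ch] += d;
      float dxh = d * gam[ch];
      sdx[ch] += dxh;
      sdxx[ch] += (double)dxh * xh[o + ch];
    }
  }
  dgamma.set_size(C); dbeta.set_size(C); db.set_size(C);
  for (int ch = 0; ch < C; ++ch) {
    dgamma[ch] = (float)dg[ch];
    dbeta[ch] = (float)dbt[ch];
  }
  const float Nf = (float)Ncol;
  fvec sdxf(C), sdxxf(C);
  for (int ch = 0; ch < C; ++ch) {
    sdxf[ch] = (float)sdx[ch];
    sdxxf[ch] = (float)sdxx[ch];
  }
  float *dz = c.dZ.memptr();
  std::vector<double> dbacc(C, 0.0);
  const float *sdxp = sdxf.memptr(), *sdxxp = sdxxf.memptr();
  for (size_t j = 0; j < Ncol; ++j) {
    const size_t o = j * C;
    for (int ch = 0; ch < C; ++ch) {
      float dxh = do_[o + ch] * gam[ch];
      // dx = invstd/N * (N*dxh - sum(dxh) - xhat * sum(dxh*xhat))
      float dA = isv[ch] / Nf *
                 (Nf * dxh - sdxp[ch] - xh[o + ch] * sdxxp[ch]);
      float v = (z[o + ch] > 0.0f) ? dA : 0.0f;
      dz[o + ch] = v;
      dbacc[ch] += v;
    }
  }
  for (int ch = 0; ch < C; ++ch) db[ch] = (float)dbacc[ch];
}

// forward for one batch collecting batch statistics per layer
// (normalization by the batch stats themselves, no dropout); used to
// re-estimate the running statistics under the current weights after
// each epoch's updates, since the exponential averages collected while
// the weights were still moving do not describe the final weights
static void forward_collect_stats(Workspace &ws, int B, const Params &p,
                                  const std::vector<ConvSpec> &specs,
                                  std::vector<fvec> &mu_out,
                                  std::vector<fvec> &var_out, int Cin,
                                  int HW) {
  fmat Xin((float *)ws.Xb.memptr(), Cin, (arma::uword)HW * B, false,
           true);
  const fmat *cur = &Xin;
  for (int l = 0; l < 4; ++l) {
    LayerBuf &c = ws.lb[l];
    im2col(*cur, specs[l], B, c.col);
    c.Z = p.W[l] * c.col;
    c.Z.each_col() += p.b[l];
    const int C = (int)c.Z.n_rows;
    const size_t Ncol = c.Z.n_cols;
    const float *z = c.Z.memptr();
    std::vector<double> sum(C, 0.0), sumsq(C, 0.0);
    for (size_t j = 0; j < Ncol; ++j) {
      const float *zc = z + j * C;
      for (int ch = 0; ch < C; ++ch) {
        float a = zc[ch] > 0.0f ? zc[ch] : 0.0f;
        sum[ch] += a; sumsq[ch] += (double)a * a;
      }
    }
    fvec mu(C), var(C), invstd(C);
    for (int ch = 0; ch < C; ++ch) {
      mu[ch] = (float)(sum[ch] / Ncol);
      double v = sumsq[ch] / Ncol - (double)mu[ch] * mu[ch];
      var[ch] = (float)std::max(v, 0.0);
      invstd[ch] = 1.0f / std::sqrt(var[ch] + BN_EPS);
    }
    mu_out[l] += mu;
    var_out[l] += var;
    float *out = c.out.memptr();
    const float *gam = p.gamma[l].memptr();
    const float *bet = p.beta[l].memptr();
    for (size_t j = 0; j < Ncol; ++j) {
      const size_t o = j * C;
      const float *zc = z + o;
      for (int ch = 0; ch < C; ++ch) {
        float a = zc[ch] > 0.0f ? zc[ch] : 0.0f;
        out[o + ch] = gam[ch] * (a - mu[ch]) * invstd[ch] + bet[ch];
      }
    }
    cur = &c.out;
  }
}

// eval-mode forward (running statistics, no dropout)
static fmat forward_eval(const fmat &Xr, int B, const Params &p,
                         const std::vector<ConvSpec> &specs, fmat &feat) {
  fmat cur = Xr;
  for (int l = 0; l < 4; ++l) {
    const ConvSpec &s = specs[l];
    fmat col((arma::uword)9 * s.Cin,
             (arma::uword)s.Hout * s.Wout * B, arma::fill::zeros);
    im2col(cur, s, B, col);
    fmat Z = p.W[l] * col;
    Z.each_col() += p.b[l];
    const int C = (int)Z.n_rows;
    fvec invstd = 1.0f / arma::sqrt(p.rvar[l] + BN_EPS);
    const float *gam = p.gamma[l].memptr();
    const float *bet = p.beta[l].memptr();
    const float *muv = p.rmean[l].memptr();
    const float *isv = invstd.memptr();
    float *z = Z.memptr();
    const size_t Ncol = Z.n_cols;
    for (size_t j = 0; j < Ncol; ++j) {
      const size_t o = j * C;
      for (int ch = 0; ch < C; ++ch) {
        float a = z[o + ch] > 0.0f ? z[o + ch] : 0.0f;
        z[o + ch] = gam[ch] * (a - muv[ch]) * isv[ch] + bet[ch];
      }
    }
    cur = std::move(Z);
  }
  const ConvSpec &last = specs[3];
  const int P = last.Hout * last.Wout;
  feat.set_size(last.Cout, B);
  for (int b = 0; b < B; ++b)
    feat.col(b) = arma::mean(cur.cols((arma::uword)b * P,
                                      (arma::uword)(b + 1) * P - 1), 1);
  fmat logits = p.W[4] * feat;
  logits.each_col() += p.b[4];
  return logits;
}

static fmat softmax_cols(const fmat &logits) {
  fmat z = logits.each_row() - arma::max(logits, 0);
  z = arma::exp(z);
  arma::frowvec s = arma::sum(z, 0);
  z.each_row() /= s;
  return z;
}

struct Adam {
  std::vector<fmat> mW, vW;
  std::vector<fvec> mb, vb, mg, vg, mbe, vbe;
  long t = 0;
  void init(const Params &p) {
    for (int l = 0; l < 5; ++l) {
      mW.push_back(fmat(arma::size(p.W[l]), arma::fill::zeros));
      vW.push_back(fmat(arma::size(p.W[l]), arma::fill::zeros));
      mb.push_back(fvec(p.b[l].n_elem, arma::fill::zeros));
      vb.push_back(fvec(p.b[l].n_elem, arma::fill::zeros));
    }
    for (int l = 0; l < 4; ++l) {
      mg.push_back(fvec(p.gamma[l].n_elem, arma::fill::zeros));
      vg.push_back(fvec(p.gamma[l].n_elem, arma::fill::zeros));
      mbe.push_back(fvec(p.beta[l].n_elem, arma::fill::zeros));
      vbe.push_back(fvec(p.beta[l].n_elem, arma::fill::zeros));
    }
  }
  template <class T>
  void step_one(T &w, const T &g, T &m, T &v, float lr) {
    const float b1 = 0.9f, b2 = 0.999f, eps = 1e-8f;
    m = b1 * m + (1 - b1) * g;
    v = b2 * v + (1 - b2) * (g % g);
    float c1 = 1.0f - std::pow(b1, (float)t);
    float c2 = 1.0f - std::pow(b2, (float)t);
    w -= lr * (m / c1) / (arma::sqrt(v / c2) + eps);
  }
};

static double eval_accuracy(const fmat &X, const arma::ivec &y,
                            const Params &p,
                            const std::vector<ConvSpec> &specs, int Cin,
                            int HW) {
  const int N = (int)y.n_elem;
  int correct = 0;
  const int chunk = 256;
  for (int s0 = 0; s0 < N; s0 += chunk) {
    int B = std::min(chunk, N - s0);
    fmat Xb = X.cols(s0, s0 + B - 1);
    fmat Xr((float *)Xb.memptr(), Cin, (arma::uword)HW * B, false, true);
    fmat feat;
    fmat logits = forward_eval(Xr, B, p, specs, feat);
    for (int b = 0; b < B; ++b)
      if ((int)logits.col(b).index_max() == y[s0 + b]) ++correct;
  }
  return (double)correct / N;
}

// [[Rcpp::export(name = ".cnn_train")]]
List cnn_train(NumericMatrix Xr_, IntegerVector y_, NumericMatrix Xval_,
               IntegerVector yval_, List params, IntegerVector dims,
               IntegerVector widths, int n_classes, double lr, int batch,
               double dropout, int epochs, int patience, double stop_acc,
               int seed, bool verbose) {
  const int Cin = dims[0], H = dims[1], W = dims[2];
  const int HW = H * W;
  std::vector<ConvSpec> specs = make_specs(Cin, H, W, widths[0], widths[1]);
  Params p = params_from_list(params);
  // borrow the R matrices (no double copy), then downcast once to float
  const arma::mat Xd(Xr_.begin(), Xr_.nrow(), Xr_.ncol(), false, true);
  const arma::mat Xvd(Xval_.begin(), Xval_.nrow(), Xval_.ncol(), false,
                      true);
  fmat X = arma::conv_to<fmat>::from(Xd);
  fmat Xval = arma::conv_to<fmat>::from(Xvd);
  arma::ivec y = arma::conv_to<arma::ivec>::from(as<arma::vec>(y_));
  arma::ivec yval = arma::conv_to<arma::ivec>::from(as<arma::vec>(yval_));
  const int N = (int)y.n_elem;
  std::mt19937 rng((unsigned)seed + 1u);
  FastRng drop_rng(((uint64_t)(unsigned)seed << 20) + 0xABCDu);
  Adam adam;
  adam.init(p);
  std::vector<double> hist_loss, hist_val;
  Params best = p;
  double best_acc = -1.0;
  int best_epoch = 0;
  std::vector<int> order(N);
  for (int i = 0; i < N; ++i) order[i] = i;

  Workspace ws_full, ws_rem;
  const int B_full = std::min(batch, N);
  ws_full.init(B_full, (int)X.n_rows, specs, dropout > 0);
  const int B_rem = N % batch;
  if (B_rem && N > batch)
    ws_rem.init(B_rem, (int)X.n_rows, specs, dropout > 0);

  std::vector<fmat> dW(4);
  std::vector<fvec> db(4), dg(4), dbe(4);
  std::vector<char> bn_seen(4, 0);
  const ConvSpec &last = specs[3];
  const int P4 = last.Hout * last.Wout;

  for (int epoch = 1; epoch <= epochs; ++epoch) {
    std::shuffle(order.begin(), order.end(), rng);
    double loss_sum = 0.0;
    int n_batches = 0;
    for (int s0 = 0; s0 < N; s0 += batch) {
      int B = std::min(batch, N - s0);
      Workspace &ws = (B == B_full) ? ws_full : ws_rem;
      arma::ivec yb(B);
      for (int b = 0; b < B; ++b) {
        ws.Xb.col(b) = X.col(order[s0 + b]);
        yb[b] = y[order[s0 + b]];
      }
      fmat Xin((float *)ws.Xb.memptr(), Cin, (arma::uword)HW * B, false,
               true);

      // forward
      {
        const fmat *cur = &Xin;
        for (int l = 0; l < 4; ++l) {
          LayerBuf &c = ws.lb[l];
          im2col(*cur, specs[l], B, c.col);
          c.Z = p.W[l] * c.col;
          c.Z.each_col() += p.b[l];
          block_forward_train(p, l, (float)dropout, drop_rng, c,
                              !bn_seen[l]);
          bn_seen[l] = 1;
          cur = &c.out;
        }
      }
      for (int b = 0; b < B; ++b)
        ws.feat.col(b) = arma::mean(
            ws.lb[3].out.cols((arma::uword)b * P4,
                              (arma::uword)(b + 1) * P4 - 1), 1);
      fmat logits = p.W[4] * ws.feat;
      logits.each_col() += p.b[4];
      fmat probs = softmax_cols(logits);
      double loss = 0.0;
      for (int b = 0; b < B; ++b)
        loss -= std::log(std::max(probs(yb[b], b), 1e-12f));
      loss /= B;
      loss_sum += loss;
      ++n_batches;

      // backward
      fmat dlogits = probs;
      for (int b = 0; b < B; ++b) dlogits(yb[b], b) -= 1.0f;
      dlogits /= (float)B;
      fmat dWfc = dlogits * ws.feat.t();
      fvec dbfc = arma::sum(dlogits, 1);
      ws.dfeat = p.W[4].t() * dlogits;
      {
        float *dc = ws.dcur4.memptr();
        const float *df = ws.dfeat.memptr();
        const int C4 = last.Cout;
        const float invP = 1.0f / (float)P4;
        for (int b = 0; b < B; ++b)
          for (int pos = 0; pos < P4; ++pos)
            for (int ch = 0; ch < C4; ++ch)
              dc[((size_t)b * P4 + pos) * C4 + ch] =
                  df[(size_t)b * C4 + ch] * invP;
      }

      fmat *dout = &ws.dcur4;
      for (int l = 3; l >= 0; --l) {
        LayerBuf &c = ws.lb[l];
        block_backward(*dout, p, l, c, dg[l], dbe[l], db[l]);
        dW[l] = c.dZ * c.col.t();
        if (l > 0) {
          c.dcol = p.W[l].t() * c.dZ;
          ws.dX[l - 1].zeros();
          col2im_add(c.dcol, specs[l], B, ws.dX[l - 1]);
          dout = &ws.dX[l - 1];
        }
      }

      ++adam.t;
      for (int l = 0; l < 4; ++l) {
        adam.step_one(p.W[l], dW[l], adam.mW[l], adam.vW[l], (float)lr);
        adam.step_one(p.b[l], db[l], adam.mb[l], adam.vb[l], (float)lr);
        adam.step_one(p.gamma[l], dg[l], adam.mg[l], adam.vg[l],
                      (float)lr);
        adam.step_one(p.beta[l], dbe[l], adam.mbe[l], adam.vbe[l],
                      (float)lr);
      }
      adam.step_one(p.W[4], dWfc, adam.mW[4], adam.vW[4], (float)lr);
      adam.step_one(p.b[4], dbfc, adam.mb[4], adam.vb[4], (float)lr);
      Rcpp::checkUserInterrupt();
    }
    // re-estimate BN running statistics under the updated weights
    // (average of batch statistics over a few shuffled batches)
    {
      std::vector<fvec> mu_acc(4), var_acc(4);
      for (int l = 0; l < 4; ++l) {
        mu_acc[l].zeros(p.gamma[l].n_elem);
        var_acc[l].zeros(p.gamma[l].n_elem);
      }
      int K = std::min(8, std::max(1, N / B_full));
      for (int k = 0; k < K; ++k) {
        for (int b = 0; b < B_full; ++b)
          ws_full.Xb.col(b) = X.col(order[(k * B_full + b) % N]);
        forward_collect_stats(ws_full, B_full, p, specs, mu_acc,
                              var_acc, Cin, HW);
      }
      for (int l = 0; l < 4; ++l) {
        p.rmean[l] = mu_acc[l] / (float)K;
        p.rvar[l] = var_acc[l] / (float)K;
      }
    }
    double epoch_loss = loss_sum / std::max(1, n_batches);
    double val_acc = yval.n_elem
                         ? eval_accuracy(Xval, yval, p, specs, Cin, HW)
                         : NA_REAL;
    hist_loss.push_back(epoch_loss);
    hist_val.push_back(val_acc);
    if (verbose)
      Rcout << "epoch " << epoch << " loss " << epoch_loss << " val_acc "
            << val_acc << "\n";
    if (yval.n_elem && val_acc > best_acc) {
      best_acc = val_acc;
      best = p;
      best_epoch = epoch;
    }
    if (yval.n_elem) {
      if (best_acc >= stop_acc) break;
      if (epoch - best_epoch >= patience) break;
    }
  }
  if (!yval.n_elem) { best = p; best_epoch = (int)hist_loss.size(); }
  return List::create(_["params"] = params_to_list(best),
                      _["train_loss"] = wrap(hist_loss),
                      _["val_accuracy"] = wrap(hist_val),
                      _["best_epoch"] = best_epoch,
                      _["best_val_accuracy"] = best_acc);
}

// [[Rcpp::export(name = ".cnn_predict")]]
NumericMatrix cnn_predict(List params, NumericMatrix X_, IntegerVector dims,
                          IntegerVector widths, int n_classes) {
  const int Cin = dims[0], H = dims[1], W = dims[2];
  const int HW = H * W;
  std::vector<ConvSpec> specs = make_specs(Cin, H, W, widths[0], widths[1]);
  Params p = params_from_list(params);
  const arma::mat Xd(X_.begin(), X_.nrow(), X_.ncol(), false, true);
  fmat X = arma::conv_to<fmat>::from(Xd);
  const int N = (int)X.n_cols;
  NumericMatrix out(N, n_classes);
  const int chunk = 256;
  for (int s0 = 0; s0 < N; s0 += chunk) {
    int B = std::min(chunk, N - s0);
    fmat Xb = X.cols(s0, s0 + B - 1);
    fmat Xr((float *)Xb.memptr(), Cin, (arma::uword)HW * B, false, true);
    fmat feat;
    fmat logits = forward_eval(Xr, B, p, specs, feat);
    fmat probs = softmax_cols(logits);
    for (int b = 0; b < B; ++b)
      for (int k = 0; k < n_classes; ++k) out(s0 + b, k) = probs(k, b);
  }
  return out;
}
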