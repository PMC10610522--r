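// Native U-Net encoder-decoder for multi-class segmentation.
//
// Feature maps are stored as single-precision matrices of shape
// (N*H*W x channels): one contiguous column per channel, pixel index
// p = (n*H + y)*W + x.  With this layout im2col for a 3x3 convolution is
// nine large shifted copies per channel and every convolution is one GEMM
// over the im2col buffer.  Training uses batch statistics in the
// normalization layers and Adam updates; inference uses running
// statistics.  All randomness (weight initialization) is driven by one
// std::mt19937 seed.
#include <RcppArmadillo.h>
#include <random>
#include <vector>
#include <string>
#include <cstring>

// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::fmat;
using arma::fvec;
using arma::frowvec;

// ---------------------------------------------------------------- params

struct Param {
  std::string name;
  fmat w, g, m, v;
  void setup(const std::string& nm, int r, int c) {
    name = nm;
    w.set_size(r, c);
    g.zeros(r, c);
    m.zeros(r, c);
    v.zeros(r, c);
  }
};

// contiguous per-column broadcasts (y.col(c) op= s[c])
static inline void col_add(fmat& y, const float* s) {
  for (arma::uword c = 0; c < y.n_cols; ++c) y.col(c) += s[c];
}
static inline void col_sub(fmat& y, const float* s) {
  for (arma::uword c = 0; c < y.n_cols; ++c) y.col(c) -= s[c];
}
static inline void col_mul(fmat& y, const float* s) {
  for (arma::uword c = 0; c < y.n_cols; ++c) y.col(c) *= s[c];
}

struct Adam {
  double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long t = 0;
  void step(std::vector<Param*>& ps, double lr) {
    ++t;
    const float c1 = (float)(1.0 - std::pow(b1, (double)t));
    const float c2 = (float)(1.0 - std::pow(b2, (double)t));
    const float fb1 = (float)b1, fb2 = (float)b2, flr = (float)lr,
                fe = (float)eps;
    for (Param* p : ps) {
      float* w = p->w.memptr();
      float* g = p->g.memptr();
      float* m = p->m.memptr();
      float* v = p->v.memptr();
      const size_t n = p->w.n_elem;
      for (size_t i = 0; i < n; ++i) {
        m[i] = fb1 * m[i] + (1.0f - fb1) * g[i];
        v[i] = fb2 * v[i] + (1.0f - fb2) * g[i] * g[i];
        w[i] -= flr * (m[i] / c1) / (std::sqrt(v[i] / c2) + fe);
      }
    }
  }
};

// ------------------------------------------------------------- im2col 3x3
//
// zero-padded 3x3 neighborhoods; column kidx*C + c of `cols` holds channel
// c shifted by kernel offset (ky, kx), kidx = (ky+1)*3 + (kx+1)

static void zero_borders(float* dst, int ky, int kx, int H, int W, int N) {
  if (ky == -1)
    for (int n = 0; n < N; ++n)
      std::memset(dst + (size_t)n * H * W, 0, (size_t)W * sizeof(float));
  if (ky == 1)
    for (int n = 0; n < N; ++n)
      std::memset(dst + ((size_t)n * H + (H - 1)) * W, 0,
                  (size_t)W * sizeof(float));
  if (kx != 0) {
    const int badx = (kx == 1) ? W - 1 : 0;
    for (int n = 0; n < N; ++n)
      for (int y = 0; y < H; ++y)
        dst[((size_t)n * H + y) * W + badx] = 0.0f;
  }
}

static void im2col3(const fmat& x, int C, int H, int W, int N, fmat& cols) {
  const size_t HW = (size_t)H * W;
  const size_t M = (size_t)N * HW;
  cols.set_size(M, 9 * C);
  for (int ky = -1; ky <= 1; ++ky) {
    for (int kx = -1; kx <= 1; ++kx) {
      const int kidx = (ky + 1) * 3 + (kx + 1);
      const long off = (long)ky * W + kx;  // src = dst + off
      const long lo = std::max<long>(0, -off);
      const long hi = std::min<long>((long)HW, (long)HW - off);
      for (int c = 0; c < C; ++c) {
        float* dst = cols.colptr((size_t)kidx * C + c);
        const float* src = x.colptr(c);
        for (int n = 0; n < N; ++n) {
          const size_t base = (size_t)n * HW;
          if (lo > 0) std::memset(dst + base, 0, lo * sizeof(float));
          if (hi > lo)
            std::memcpy(dst + base + lo, src + base + lo + off,
                        (hi - lo) * sizeof(float));
          if ((size_t)hi < HW)
            std::memset(dst + base + hi, 0, (HW - hi) * sizeof(float));
        }
        zero_borders(dst, ky, kx, H, W, N);
      }
    }
  }
}

// ----------------------------------------------------------------- layers

struct Conv {
  int cin = 0, cout = 0, k = 3;
  Param W,  // (k*k*cin, cout)
      b;    // (cout, 1)
  fmat cols;    // cache (k==3)
  fmat dycols, wrot;  // scratch for the backward pass
  fmat x1;      // cache (k==1)
  int H = 0, Wd = 0, N = 0;

  void setup(const std::string& nm, int cin_, int cout_, int k_) {
    cin = cin_; cout = cout_; k = k_;
    W.setup(nm + ".W", k * k * cin, cout);
    b.setup(nm + ".b", cout, 1);
  }
  int n_params() const { return (int)(W.w.n_elem + b.w.n_elem); }

  fmat forward(const fmat& x, int H_, int W_, int N_) {
    H = H_; Wd = W_; N = N_;
    fmat y;
    if (k == 3) {
      im2col3(x, cin, H, Wd, N, cols);
      y = cols * W.w;
    } else {
      x1 = x;
      y = x * W.w;
    }
    col_add(y, b.w.colptr(0));
    return y;
  }
  fmat backward(const fmat& dy, bool need_dx = true) {
    b.g = arma::sum(dy, 0).t();
    if (k == 3) {
      W.g = cols.t() * dy;
      if (!need_dx) return fmat();
      // input gradient as a direct convolution of dy with the spatially
      // flipped kernel (the transpose of a zero-padded 3x3 convolution);
      // keeps the GEMM inner dimension at 9*cout instead of cout
      im2col3(dy, cout, H, Wd, N, dycols);
      wrot.set_size(9 * cout, cin);
      for (int kk = 0; kk < 9; ++kk)
        wrot.rows(kk * cout, kk * cout + cout - 1) =
            W.w.rows((8 - kk) * cin, (8 - kk) * cin + cin - 1).t();
      return dycols * wrot;
    }
    W.g = x1.t() * dy;
    return dy * W.w.t();
  }
};

struct BatchNorm {
  int C = 0;
  Param g, b;  // (C, 1)
  fvec run_m, run_v;
  float mom = 0.1f, eps = 1e-5f;
  fmat xhat;
  frowvec istd, mu_cache;

  void setup(const std::string& nm, int C_) {
    C = C_;
    g.setup(nm + ".gamma", C, 1);
    b.setup(nm + ".beta", C, 1);
    run_m.zeros(C);
    run_v.ones(C);
  }
  int n_params() const { return 2 * C; }

  fmat forward(const fmat& x, bool train) {
    if (train) {
      const double M = (double)x.n_rows;
      frowvec mu = arma::mean(x, 0);
      fmat xc = x;
      col_sub(xc, mu.memptr());
      frowvec var(C);
      for (int c = 0; c < C; ++c)
        var(c) = arma::dot(xc.col(c), xc.col(c)) / (float)M;
      istd = 1.0f / arma::sqrt(var + eps);
      mu_cache = mu;
      col_mul(xc, istd.memptr());
      xhat = std::move(xc);
      const float ub = M > 1 ? (float)(M / (M - 1.0)) : 1.0f;
      run_m = (1.0f - mom) * run_m + mom * mu.t();
      run_v = (1.0f - mom) * run_v + mom * (var.t() * ub);
      fmat y(x.n_rows, C);
      for (int c = 0; c < C; ++c)
        y.col(c) = xhat.col(c) * g.w(c, 0) + b.w(c, 0);
      return y;
    }
    frowvec sc = frowvec(g.w.t()) / arma::sqrt(frowvec(run_v.t()) + eps);
    frowvec sh = frowvec(b.w.t()) - sc % frowvec(run_m.t());
    fmat y(x.n_rows, C);
    for (int c = 0; c < C; ++c) y.col(c) = x.col(c) * sc(c) + sh(c);
    return y;
  }
  fmat backward(const fmat& dy) {
    const float M = (float)dy.n_rows;
    g.g.set_size(C, 1);
    b.g.set_size(C, 1);
    fvec s1(C), s2(C);
    fmat dx = dy;
    col_mul(dx, g.w.colptr(0));  // dx = dxhat
    for (int c = 0; c < C; ++c) {
      g.g(c, 0) = arma::dot(dy.col(c), xhat.col(c));
      b.g(c, 0) = arma::accu(dy.col(c));
      s1(c) = arma::accu(dx.col(c));
      s2(c) = arma::dot(dx.col(c), xhat.col(c));
    }
    for (int c = 0; c < C; ++c) {
      dx.col(c) -= s1(c) / M;
      dx.col(c) -= xhat.col(c) * (s2(c) / M);
      dx.col(c) *= istd(c);
    }
    return dx;
  }
};

// convolution -> rectifier -> batch normalization, the per-operation order
// used throughout the architecture (including the final 1x1 classifier)
struct ConvBN {
  Conv conv;
  BatchNorm bn;
  fvec relu_thr;  // per-channel xhat threshold equivalent to pre-BN y > 0
  std::string block, opname;

  void setup(const std::string& nm, int cin, int cout, int k,
             const std::string& block_, const std::string& opname_) {
    conv.setup(nm, cin, cout, k);
    bn.setup(nm, cout);
    block = block_; opname = opname_;
  }
  int n_params() const { return conv.n_params() + bn.n_params(); }

  fmat forward(const fmat& x, int H, int W, int N, bool train) {
    fmat y = conv.forward(x, H, W, N);
    float* p = y.memptr();
    for (size_t i = 0; i < y.n_elem; ++i)
      if (p[i] < 0.0f) p[i] = 0.0f;
    fmat out = bn.forward(y, train);
    if (train) {
      // y > 0  <=>  xhat > (0 - mu) * istd, per channel (istd > 0)
      relu_thr.set_size(bn.C);
      for (int c = 0; c < bn.C; ++c)
        relu_thr(c) = -bn.mu_cache(c) * bn.istd(c);
    }
    return out;
  }
  fmat backward(const fmat& dy, bool need_dx = true) {
    fmat d = bn.backward(dy);
    for (int c = 0; c < bn.C; ++c) {
      float* dp = d.colptr(c);
      const float* xp = bn.xhat.colptr(c);
      const float thr = relu_thr(c);
      const size_t M = d.n_rows;
      for (size_t i = 0; i < M; ++i) dp[i] *= (float)(xp[i] > thr);
    }
    return conv.backward(d, need_dx);
  }
};

struct MaxPool {
  std::vector<size_t> idx;  // chosen input pixel per (output pixel, channel)
  int C = 0, H = 0, W = 0, N = 0;

  fmat forward(const fmat& x, int C_, int H_, int W_, int N_) {
    C = C_; H = H_; W = W_; N = N_;
    const int Ho = H / 2, Wo = W / 2;
    const size_t Mo = (size_t)N * Ho * Wo;
    fmat y(Mo, C);
    idx.resize(Mo * C);
    for (int c = 0; c < C; ++c) {
      const float* xs = x.colptr(c);
      float* ys = y.colptr(c);
      size_t* id = idx.data() + (size_t)c * Mo;
      size_t po = 0;
      for (int n = 0; n < N; ++n)
        for (int yo = 0; yo < Ho; ++yo) {
          const size_t r0 = ((size_t)n * H + 2 * yo) * W;
          for (int xo = 0; xo < Wo; ++xo, ++po) {
            const size_t p00 = r0 + 2 * xo;
            size_t best = p00;
            float bv = xs[p00];
            if (xs[p00 + 1] > bv) { bv = xs[p00 + 1]; best = p00 + 1; }
            if (xs[p00 + W] > bv) { bv = xs[p00 + W]; best = p00 + W; }
            if (xs[p00 + W + 1] > bv) { bv = xs[p00 + W + 1]; best = p00 + W + 1; }
            ys[po] = bv;
            id[po] = best;
          }
        }
    }
    return y;
  }
  fmat backward(const fmat& dy) {
    const size_t Mo = dy.n_rows;
    fmat dx((size_t)N * H * W, C, arma::fill::zeros);
    for (int c = 0; c < C; ++c) {
      const float* ds = dy.colptr(c);
      float* dd = dx.colptr(c);
      const size_t* id = idx.data() + (size_t)c * Mo;
      for (size_t po = 0; po < Mo; ++po) dd[id[po]] += ds[po];
    }
    return dx;
  }
};

// 2x2 transposed convolution with stride 2 (bias, no batch norm)
struct ConvT {
  int cin = 0, cout = 0;
  Param W,  // (cin, 4*cout); column q*cout + c is offset q = dy*2 + dx
      b;
  fmat xin;
  int H = 0, Wd = 0, N = 0;
  std::string block;

  void setup(const std::string& nm, int cin_, int cout_,
             const std::string& block_) {
    cin = cin_; cout = cout_; block = block_;
    W.setup(nm + ".W", cin, 4 * cout);
    b.setup(nm + ".b", cout, 1);
  }
  int n_params() const { return (int)(W.w.n_elem + b.w.n_elem); }

  fmat forward(const fmat& x, int H_, int W_, int N_) {
    H = H_; Wd = W_; N = N_;
    xin = x;
    fmat cols = x * W.w;  // (Min, 4*cout)
    const int Ho = 2 * H, Wo = 2 * Wd;
    fmat y((size_t)N * Ho * Wo, cout);
    for (int c = 0; c < cout; ++c) {
      float* ys = y.colptr(c);
      for (int q = 0; q < 4; ++q) {
        const int dy_ = q / 2, dx_ = q % 2;
        const float* cs = cols.colptr((size_t)q * cout + c);
        size_t p = 0;
        for (int n = 0; n < N; ++n)
          for (int yy = 0; yy < H; ++yy) {
            size_t po = ((size_t)n * Ho + 2 * yy + dy_) * Wo + dx_;
            for (int xx = 0; xx < Wd; ++xx, ++p, po += 2) ys[po] = cs[p];
          }
      }
    }
    col_add(y, b.w.colptr(0));
    return y;
  }
  fmat backward(const fmat& dy) {
    const int Ho = 2 * H, Wo = 2 * Wd;
    fmat dcols((size_t)N * H * Wd, 4 * cout);
    for (int c = 0; c < cout; ++c) {
      const float* ds = dy.colptr(c);
      for (int q = 0; q < 4; ++q) {
        const int dy_ = q / 2, dx_ = q % 2;
        float* cs = dcols.colptr((size_t)q * cout + c);
        size_t p = 0;
        for (int n = 0; n < N; ++n)
          for (int yy = 0; yy < H; ++yy) {
            size_t po = ((size_t)n * Ho + 2 * yy + dy_) * Wo + dx_;
            for (int xx = 0; xx < Wd; ++xx, ++p, po += 2) cs[p] = ds[po];
          }
      }
    }
    b.g = arma::sum(dy, 0).t();
    W.g = xin.t() * dcols;
    return dcols * W.w.t();
  }
};

// ------------------------------------------------------------------ U-Net

struct UNet {
  std::vector<int> enc;
  int bott = 0, fmid = 0, K = 0, L = 0;

  std::vector<ConvBN> ea, eb;
  std::vector<MaxPool> pools;
  ConvBN ba, bb;
  std::vector<ConvT> ups;      // [0] after bottleneck, [j] after expansion L-j+1
  std::vector<ConvBN> da, db;  // expansions, deepest first
  ConvBN fa, fb;

  std::vector<Param*> params;
  std::vector<ConvBN*> convbn_seq;
  Adam opt;

  std::vector<fmat> skips, dskips;

  void build(const std::vector<int>& enc_, int bott_, int fmid_, int K_,
             int seed) {
    enc = enc_; bott = bott_; fmid = fmid_; K = K_; L = (int)enc.size();
    ea.resize(L); eb.resize(L); pools.resize(L);
    ups.resize(L); da.resize(L); db.resize(L);
    skips.resize(L); dskips.resize(L);

    const std::string op3 = "Conv2d 3x3, ReLU, BatchNorm2d";
    const std::string op1 = "Conv2d 1x1, ReLU, BatchNorm2d";

    int cin = 1;
    for (int i = 0; i < L; ++i) {
      const std::string blk = "Contraction " + std::to_string(i + 1);
      ea[i].setup("c" + std::to_string(i + 1) + "a", cin, enc[i], 3, blk, op3);
      eb[i].setup("c" + std::to_string(i + 1) + "b", enc[i], enc[i], 3, blk, op3);
      cin = enc[i];
    }
    ba.setup("b1", enc[L - 1], bott, 3, "Bottleneck", op3);
    bb.setup("b2", bott, bott, 3, "Bottleneck", op3);
    ups[0].setup("up1", bott, bott, "Bottleneck");
    for (int j = 0; j < L; ++j) {
      const int upch = (j == 0) ? bott : enc[L - j];
      const int skch = enc[L - 1 - j];
      const std::string blk = "Expansion " + std::to_string(L - j);
      da[j].setup("e" + std::to_string(L - j) + "a", upch + skch, skch, 3, blk,
                  op3);
      db[j].setup("e" + std::to_string(L - j) + "b", skch, skch, 3, blk, op3);
      if (j < L - 1)
        ups[j + 1].setup("up" + std::to_string(j + 2), skch, skch, blk);
    }
    fa.setup("fin3", enc[0], fmid, 3, "Final", op3);
    fb.setup("fin1", fmid, K, 1, "Final", op1);

    params.clear(); convbn_seq.clear();
    auto reg_cbn = [&](ConvBN& c) {
      params.push_back(&c.conv.W); params.push_back(&c.conv.b);
      params.push_back(&c.bn.g);   params.push_back(&c.bn.b);
      convbn_seq.push_back(&c);
    };
    auto reg_up = [&](ConvT& u) {
      params.push_back(&u.W); params.push_back(&u.b);
    };
    for (int i = 0; i < L; ++i) { reg_cbn(ea[i]); reg_cbn(eb[i]); }
    reg_cbn(ba); reg_cbn(bb); reg_up(ups[0]);
    for (int j = 0; j < L; ++j) {
      reg_cbn(da[j]); reg_cbn(db[j]);
      if (j < L - 1) reg_up(ups[j + 1]);
    }
    reg_cbn(fa); reg_cbn(fb);

    init_weights(seed);
  }

  // fan-in uniform init, U(-1/sqrt(fan_in), 1/sqrt(fan_in)) for convolution
  // weights and biases; batch-norm scale 1, shift 0
  void init_weights(int seed) {
    std::mt19937 gen((unsigned)seed);
    auto fill_unif = [&](fmat& w, float bound) {
      std::uniform_real_distribution<float> d(-bound, bound);
      for (arma::uword i = 0; i < w.n_elem; ++i) w(i) = d(gen);
    };
    for (Param* p : params) {
      p->m.zeros(); p->v.zeros(); p->g.zeros();
    }
    auto init_cbn = [&](ConvBN& c) {
      const float bound =
          1.0f / std::sqrt((float)(c.conv.cin * c.conv.k * c.conv.k));
      fill_unif(c.conv.W.w, bound);
      fill_unif(c.conv.b.w, bound);
      c.bn.g.w.ones(); c.bn.b.w.zeros();
      c.bn.run_m.zeros(); c.bn.run_v.ones();
    };
    auto init_up = [&](ConvT& u) {
      const float bound = 1.0f / std::sqrt((float)(u.cin * 4));
      fill_unif(u.W.w, bound);
      fill_unif(u.b.w, bound);
    };
    for (int i = 0; i < L; ++i) { init_cbn(ea[i]); init_cbn(eb[i]); }
    init_cbn(ba); init_cbn(bb); init_up(ups[0]);
    for (int j = 0; j < L; ++j) {
      init_cbn(da[j]); init_cbn(db[j]);
      if (j < L - 1) init_up(ups[j + 1]);
    }
    init_cbn(fa); init_cbn(fb);
    opt = Adam();
  }

  fmat forward(const fmat& x0, int H, int W, int N, bool train) {
    fmat x = x0;
    int h = H, w = W;
    for (int i = 0; i < L; ++i) {
      x = ea[i].forward(x, h, w, N, train);
      x = eb[i].forward(x, h, w, N, train);
      skips[i] = x;
      x = pools[i].forward(x, enc[i], h, w, N);
      h /= 2; w /= 2;
    }
    x = ba.forward(x, h, w, N, train);
    x = bb.forward(x, h, w, N, train);
    x = ups[0].forward(x, h, w, N);
    h *= 2; w *= 2;
    for (int j = 0; j < L; ++j) {
      x = arma::join_rows(x, skips[L - 1 - j]);
      x = da[j].forward(x, h, w, N, train);
      x = db[j].forward(x, h, w, N, train);
      if (j < L - 1) {
        x = ups[j + 1].forward(x, h, w, N);
        h *= 2; w *= 2;
      }
    }
    x = fa.forward(x, h, w, N, train);
    x = fb.forward(x, h, w, N, train);
    return x;  // (N*H*W, K) class scores
  }

  void backward(const fmat& dz) {
    fmat d = fb.backward(dz);
    d = fa.backward(d);
    for (int j = L - 1; j >= 0; --j) {
      if (j < L - 1) d = ups[j + 1].backward(d);
      d = db[j].backward(d);
      d = da[j].backward(d);
      const int upch = (j == 0) ? bott : enc[L - j];
      dskips[L - 1 - j] = d.cols(upch, d.n_cols - 1);
      d = d.cols(0, upch - 1);
    }
    d = ups[0].backward(d);
    d = bb.backward(d);
    d = ba.backward(d);
    for (int i = L - 1; i >= 0; --i) {
      d = pools[i].backward(d);
      d += dskips[i];
      d = eb[i].backward(d);
      d = ea[i].backward(d, i > 0);  // no input gradient needed at the input
    }
  }
};

// ------------------------------------------------------------ loss helpers

static double ce_loss(const fmat& z, const std::vector<int>& lab, fmat* dz) {
  const int K = (int)z.n_cols;
  const size_t M = z.n_rows;
  frowvec dummy;
  fvec mx = z.col(0);
  for (int k = 1; k < K; ++k) mx = arma::max(mx, z.col(k));
  fmat e = z;
  e.each_col() -= mx;
  e = arma::exp(e);
  fvec se = arma::sum(e, 1);
  double loss = 0.0;
  for (size_t p = 0; p < M; ++p)
    loss += std::log((double)se(p)) + (double)mx(p) - (double)z(p, lab[p]);
  loss /= (double)M;
  if (dz) {
    *dz = e.each_col() / (se * (float)M);
    for (size_t p = 0; p < M; ++p) (*dz)(p, lab[p]) -= 1.0f / (float)M;
  }
  return loss;
}

// ------------------------------------------------------- R array plumbing

// images arrive as an (H, W, N) array in [0,1]; repack to one column with
// pixel index p = (n*H + y)*W + x
static fmat frames_to_mat(const NumericVector& imgs, int& H, int& W, int& N,
                          IntegerVector sel) {
  IntegerVector dim = imgs.attr("dim");
  if (dim.size() != 3) stop("frames must be an (H, W, N) array");
  H = dim[0]; W = dim[1];
  N = sel.size();
  fmat x((size_t)N * H * W, 1);
  float* xp = x.colptr(0);
  for (int j = 0; j < N; ++j) {
    const size_t n0 = (size_t)(sel[j] - 1) * H * W;
    for (int y = 0; y < H; ++y)
      for (int xx = 0; xx < W; ++xx)
        xp[((size_t)j * H + y) * W + xx] =
            (float)imgs[n0 + (size_t)y + (size_t)H * xx];
  }
  return x;
}

static std::vector<int> labels_to_vec(const IntegerVector& labs, int H, int W,
                                      IntegerVector sel) {
  const int N = sel.size();
  std::vector<int> out((size_t)N * H * W);
  for (int j = 0; j < N; ++j) {
    const size_t n0 = (size_t)(sel[j] - 1) * H * W;
    for (int y = 0; y < H; ++y)
      for (int xx = 0; xx < W; ++xx)
        out[((size_t)j * H + y) * W + xx] =
            labs[n0 + (size_t)y + (size_t)H * xx];
  }
  return out;
}

static IntegerVector all_idx(const NumericVector& imgs) {
  IntegerVector dim = imgs.attr("dim");
  return seq_len(dim[2]);
}

// ----------------------------------------------------------------- driver

// [[Rcpp::export]]
SEXP cpp_unet_create(IntegerVector enc_channels, int bottleneck_channels,
                     int final_intermediate_channels, int num_classes,
                     int seed) {
  XPtr<UNet> p(new UNet(), true);
  std::vector<int> enc(enc_channels.begin(), enc_channels.end());
  p->build(enc, bottleneck_channels, final_intermediate_channels, num_classes,
           seed);
  return p;
}

// [[Rcpp::export]]
double cpp_unet_num_params(SEXP ptr) {
  XPtr<UNet> p(ptr);
  double tot = 0;
  for (Param* q : p->params) tot += (double)q->w.n_elem;
  return tot;
}

// [[Rcpp::export]]
DataFrame cpp_unet_audit(SEXP ptr) {
  XPtr<UNet> p(ptr);
  std::vector<std::string> block, op;
  std::vector<int> cnt;
  auto add_cbn = [&](ConvBN& c) {
    block.push_back(c.block); op.push_back(c.opname);
    cnt.push_back(c.n_params());
  };
  auto add_up = [&](ConvT& u) {
    block.push_back(u.block); op.push_back("ConvTranspose2d");
    cnt.push_back(u.n_params());
  };
  for (int i = 0; i < p->L; ++i) { add_cbn(p->ea[i]); add_cbn(p->eb[i]); }
  add_cbn(p->ba); add_cbn(p->bb); add_up(p->ups[0]);
  for (int j = 0; j < p->L; ++j) {
    add_cbn(p->da[j]); add_cbn(p->db[j]);
    if (j < p->L - 1) add_up(p->ups[j + 1]);
  }
  add_cbn(p->fa); add_cbn(p->fb);
  return DataFrame::create(_["block"] = block, _["operation"] = op,
                           _["params"] = cnt,
                           _["stringsAsFactors"] = false);
}

// [[Rcpp::export]]
IntegerVector cpp_unet_predict(SEXP ptr, NumericVector imgs) {
  XPtr<UNet> p(ptr);
  int H, W, N;
  fmat x = frames_to_mat(imgs, H, W, N, all_idx(imgs));
  fmat z = p->forward(x, H, W, N, false);
  IntegerVector out((size_t)H * W * N);
  out.attr("dim") = IntegerVector::create(H, W, N);
  const int K = p->K;
  for (int n = 0; n < N; ++n)
    for (int y = 0; y < H; ++y)
      for (int xx = 0; xx < W; ++xx) {
        const size_t prow = ((size_t)n * H + y) * W + xx;
        int best = 0;
        float bv = z(prow, 0);
        for (int k = 1; k < K; ++k)
          if (z(prow, k) > bv) { bv = z(prow, k); best = k; }  // ties: lowest
        out[(size_t)y + (size_t)H * xx + (size_t)H * W * n] = best;
      }
  return out;
}

// [[Rcpp::export]]
double cpp_unet_loss(SEXP ptr, NumericVector imgs, IntegerVector labs,
                     bool train_mode) {
  XPtr<UNet> p(ptr);
  int H, W, N;
  IntegerVector sel = all_idx(imgs);
  fmat x = frames_to_mat(imgs, H, W, N, sel);
  std::vector<int> lv = labels_to_vec(labs, H, W, sel);
  fmat z = p->forward(x, H, W, N, train_mode);
  return ce_loss(z, lv, nullptr);
}

// one inference-mode forward returning both the cross-entropy loss and the
// arg-max label maps (used for per-epoch validation)
// [[Rcpp::export]]
List cpp_unet_eval(SEXP ptr, NumericVector imgs, IntegerVector labs) {
  XPtr<UNet> p(ptr);
  int H, W, N;
  IntegerVector sel = all_idx(imgs);
  fmat x = frames_to_mat(imgs, H, W, N, sel);
  std::vector<int> lv = labels_to_vec(labs, H, W, sel);
  fmat z = p->forward(x, H, W, N, false);
  const double loss = ce_loss(z, lv, nullptr);
  IntegerVector out((size_t)H * W * N);
  out.attr("dim") = IntegerVector::create(H, W, N);
  const int K = p->K;
  for (int n = 0; n < N; ++n)
    for (int y = 0; y < H; ++y)
      for (int xx = 0; xx < W; ++xx) {
        const size_t prow = ((size_t)n * H + y) * W + xx;
        int best = 0;
        float bv = z(prow, 0);
        for (int k = 1; k < K; ++k)
          if (z(prow, k) > bv) { bv = z(prow, k); best = k; }
        out[(size_t)y + (size_t)H * xx + (size_t)H * W * n] = best;
      }
  return List::create(_["loss"] = loss, _["labels"] = out);
}

// [[Rcpp::export]]
double cpp_unet_train_epoch(SEXP ptr, NumericVector imgs, IntegerVector labs,
                            IntegerVector order, int batch, double lr) {
  XPtr<UNet> p(ptr);
  const int ntot = order.size();
  double loss_sum = 0.0;
  long nseen = 0;
  for (int s = 0; s < ntot; s += batch) {
    const int e = std::min(ntot, s + batch);
    IntegerVector sel(order.begin() + s, order.begin() + e);
    int H, W, N;
    fmat x = frames_to_mat(imgs, H, W, N, sel);
    std::vector<int> lv = labels_to_vec(labs, H, W, sel);
    fmat z = p->forward(x, H, W, N, true);
    fmat dz;
    const double l = ce_loss(z, lv, &dz);
    if (!std::isfinite(l)) stop("non-finite training loss in batch");
    p->backward(dz);
    p->opt.step(p->params, lr);
    loss_sum += l * (e - s);
    nseen += (e - s);
    Rcpp::checkUserInterrupt();
  }
  return loss_sum / (double)nseen;
}

// [[Rcpp::export]]
List cpp_unet_grads(SEXP ptr, NumericVector imgs, IntegerVector labs) {
  XPtr<UNet> p(ptr);
  int H, W, N;
  IntegerVector sel = all_idx(imgs);
  fmat x = frames_to_mat(imgs, H, W, N, sel);
  std::vector<int> lv = labels_to_vec(labs, H, W, sel);
  fmat z = p->forward(x, H, W, N, true);
  fmat dz;
  ce_loss(z, lv, &dz);
  p->backward(dz);
  List out;
  for (Param* q : p->params) {
    NumericMatrix m(q->g.n_rows, q->g.n_cols);
    for (arma::uword i = 0; i < q->g.n_elem; ++i) m[i] = q->g(i);
    out[q->name] = m;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_unet_get_weights(SEXP ptr) {
  XPtr<UNet> p(ptr);
  List out;
  for (Param* q : p->params) {
    NumericMatrix m(q->w.n_rows, q->w.n_cols);
    for (arma::uword i = 0; i < q->w.n_elem; ++i) m[i] = q->w(i);
    out[q->name] = m;
  }
  for (ConvBN* c : p->convbn_seq) {
    const std::string nm = c->bn.g.name.substr(0, c->bn.g.name.size() - 6);
    NumericVector rm(c->bn.run_m.n_elem), rv(c->bn.run_v.n_elem);
    for (arma::uword i = 0; i < c->bn.run_m.n_elem; ++i) {
      rm[i] = c->bn.run_m(i);
      rv[i] = c->bn.run_v(i);
    }
    out[nm + ".run_mean"] = rm;
    out[nm + ".run_var"] = rv;
  }
  return out;
}

// [[Rcpp::export]]
void cpp_unet_set_weights(SEXP ptr, List wts) {
  XPtr<UNet> p(ptr);
  for (Param* q : p->params) {
    if (!wts.containsElementNamed(q->name.c_str()))
      stop("missing weight tensor: " + q->name);
    NumericMatrix m = wts[q->name];
    if ((arma::uword)m.nrow() != q->w.n_rows ||
        (arma::uword)m.ncol() != q->w.n_cols)
      stop("dimension mismatch for " + q->name);
    for (arma::uword i = 0; i < q->w.n_elem; ++i) q->w(i) = (float)m[i];
  }
  for (ConvBN* c : p->convbn_seq) {
    const std::string nm = c->bn.g.name.substr(0, c->bn.g.name.size() - 6);
    if (wts.containsElementNamed((nm + ".run_mean").c_str())) {
      NumericVector rm = wts[nm + ".run_mean"], rv = wts[nm + ".run_var"];
      for (arma::uword i = 0; i < c->bn.run_m.n_elem; ++i) {
        c->bn.run_m(i) = (float)rm[i];
        c->bn.run_v(i) = (float)rv[i];
      }
    }
  }
}

// Pin the BLAS thread pool (reproducible reductions; avoids thread
// oversubscription when core quotas are smaller than the detected count).
#include <dlfcn.h>
// [[Rcpp::export]]
bool cpp_pin_blas_threads(int n) {
  typedef void (*fn_t)(int);
  fn_t f = (fn_t)dlsym(RTLD_DEFAULT, "openblas_set_num_threads");
  if (!f) return false;
  f(n);
  return true;
}

// Keep large scratch buffers on the heap between mini-batches: by default
// glibc serves multi-megabyte allocations with mmap and returns them to the
// kernel on free, so every batch re-faults its im2col buffers.  Raising the
// thresholds lets the allocator reuse them.
#ifdef __GLIBC__
#include <malloc.h>
#endif
// [[Rcpp::export]]
void cpp_tune_allocator() {
#ifdef __GLIBC__
  mallopt(M_MMAP_THRESHOLD, 512 * 1024 * 1024);
  mallopt(M_TRIM_THRESHOLD, 512 * 1024 * 1024);
#endif
}
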