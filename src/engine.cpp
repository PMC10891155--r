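// Minimal single-precision convolutional network engine used for the three
// networks of the staining framework (generator / discriminator / registration).
// Tensors are stored column-major with dims (H, W, C, N), matching R arrays.
// Convolutions run as im2col + SGEMM (Armadillo/BLAS); backprop is manual.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <random>
#include <vector>
#include <memory>

using namespace arma;

struct Tensor {
  int H = 0, W = 0, C = 0, N = 0;
  fvec v;
  Tensor() {}
  Tensor(int h, int w, int c, int n, bool zero = false) : H(h), W(w), C(c), N(n) {
    v.set_size(size_t(h) * w * c * n);
    if (zero) v.zeros();
  }
  inline size_t idx(int h, int w, int c, int n) const {
    return size_t(h) + size_t(H) * (size_t(w) + size_t(W) * (size_t(c) + size_t(C) * size_t(n)));
  }
  inline float &at(int h, int w, int c, int n) { return v[idx(h, w, c, n)]; }
  inline float at(int h, int w, int c, int n) const { return v[idx(h, w, c, n)]; }
};

enum Act { LINEAR = 0, RELU = 1, SIGMOID = 2, LEAKY = 3 };

static inline float actfun(float x, int a) {
  switch (a) {
    case RELU: return x > 0 ? x : 0.0f;
    case SIGMOID: return 1.0f / (1.0f + std::exp(-x));
    case LEAKY: return x > 0 ? x : 0.2f * x;
    default: return x;
  }
}
// derivative expressed through the pre-activation value z
static inline float actgrad_pre(float z, int a) {
  switch (a) {
    case RELU: return z > 0 ? 1.0f : 0.0f;
    case SIGMOID: { float y = 1.0f / (1.0f + std::exp(-z)); return y * (1.0f - y); }
    case LEAKY: return z > 0 ? 1.0f : 0.2f;
    default: return 1.0f;
  }
}

// ---------------------------------------------------------------------------
// Convolution layer (k x k, zero padding, stride s), fused activation.
// ---------------------------------------------------------------------------
struct ConvLayer {
  int k = 3, stride = 1, pad = 1, cin = 0, cout = 0, act = RELU;
  bool needDx = true;  // first layers can skip the input gradient
  fmat Wm;           // (cin*k*k) x cout
  fvec b;            // cout
  fmat gW; fvec gb;  // gradients
  fmat mW, vW; fvec mb, vb;  // Adam state

  // caches from the last training forward (buffers reused across steps)
  fmat col;   // (Ho*Wo*N) x (cin*k*k)
  fmat Ymat, dY, dcol;  // Ymat holds pre-activations for the act derivative
  int Hin = 0, Win = 0, Nin = 0;

  void init(std::mt19937 &rng) {
    int fan_in = cin * k * k;
    float sd = std::sqrt(2.0f / float(fan_in));
    std::normal_distribution<float> nd(0.0f, sd);
    Wm.set_size(fan_in, cout);
    for (uword j = 0; j < Wm.n_cols; j++)
      for (uword i = 0; i < Wm.n_rows; i++) Wm(i, j) = nd(rng);
    b.zeros(cout);
    gW.zeros(fan_in, cout); gb.zeros(cout);
    mW.zeros(fan_in, cout); vW.zeros(fan_in, cout);
    mb.zeros(cout); vb.zeros(cout);
  }

  void outdims(int H, int W, int &Ho, int &Wo) const {
    Ho = (H + 2 * pad - k) / stride + 1;
    Wo = (W + 2 * pad - k) / stride + 1;
  }

  void im2col(const Tensor &x, fmat &out) const {
    int Ho, Wo; outdims(x.H, x.W, Ho, Wo);
    size_t R = size_t(Ho) * Wo * x.N;
    out.set_size(R, size_t(cin) * k * k);
    for (int c = 0; c < cin; c++)
      for (int dw = 0; dw < k; dw++)
        for (int dh = 0; dh < k; dh++) {
          size_t q = size_t(dh) + k * (size_t(dw) + size_t(k) * c);
          float *dst = out.colptr(q);
          // valid output-row range for this kernel offset (branch-free core)
          int lo = std::max(0, (pad - dh + stride - 1) / stride);
          int hi = std::min(Ho, (x.H - 1 - dh + pad) / stride + 1);
          for (int n = 0; n < x.N; n++)
            for (int wo = 0; wo < Wo; wo++) {
              int w = wo * stride + dw - pad;
              size_t r0 = size_t(Ho) * (size_t(wo) + size_t(Wo) * n);
              if (w < 0 || w >= x.W) {
                std::fill(dst + r0, dst + r0 + Ho, 0.0f);
                continue;
              }
              const float *src = &x.v[x.idx(0, w, c, n)];
              float *d = dst + r0;
              for (int ho = 0; ho < lo; ho++) d[ho] = 0.0f;
              if (stride == 1) {
                const float *s = src + (lo + dh - pad);
                for (int ho = lo; ho < hi; ho++) d[ho] = s[ho - lo];
              } else {
                for (int ho = lo; ho < hi; ho++)
                  d[ho] = src[ho * stride + dh - pad];
              }
              for (int ho = hi; ho < Ho; ho++) d[ho] = 0.0f;
            }
        }
  }

  void col2im(const fmat &dc, Tensor &dx) const {
    int Ho, Wo; outdims(dx.H, dx.W, Ho, Wo);
    for (int c = 0; c < cin; c++)
      for (int dw = 0; dw < k; dw++)
        for (int dh = 0; dh < k; dh++) {
          size_t q = size_t(dh) + k * (size_t(dw) + size_t(k) * c);
          const float *src = dc.colptr(q);
          int lo = std::max(0, (pad - dh + stride - 1) / stride);
          int hi = std::min(Ho, (dx.H - 1 - dh + pad) / stride + 1);
          for (int n = 0; n < dx.N; n++)
            for (int wo = 0; wo < Wo; wo++) {
              int w = wo * stride + dw - pad;
              if (w < 0 || w >= dx.W) continue;
              size_t r0 = size_t(Ho) * (size_t(wo) + size_t(Wo) * n);
              float *dst = &dx.v[dx.idx(0, w, c, n)];
              const float *s = src + r0;
              if (stride == 1) {
                float *d = dst + (lo + dh - pad);
                for (int ho = lo; ho < hi; ho++) d[ho - lo] += s[ho];
              } else {
                for (int ho = lo; ho < hi; ho++)
                  dst[ho * stride + dh - pad] += s[ho];
              }
            }
        }
  }

  // rearranged weights (C x k*k*F) for the direct stride-1 path:
  // column o*cout+f holds W[dh + k*(dw + k*c), f] with o = dh + k*dw
  fmat Wall;
  Tensor xin;   // cached input (training)
  fvec zcache;  // cached pre-activations, layout of the output tensor
  fmat Dsh;     // shifted upstream-gradient buffer

  void buildWall() {
    int kk = k * k;
    Wall.set_size(cin, kk * cout);
    for (int c = 0; c < cin; c++)
      for (int o = 0; o < kk; o++)
        for (int f = 0; f < cout; f++)
          Wall(c, size_t(o) * cout + f) = Wm(size_t(o) + size_t(kk) * c, f);
  }

  bool direct() const { return stride == 1 && pad == (k - 1) / 2; }

  // accumulate P block (shifted by (sh, sw), zero outside) into Y
  static void shiftAdd(const float *P, float *Y, int H, int W, int sh, int sw) {
    int wlo = std::max(0, -sw), whi = std::min(W, W - sw);
    int hlo = std::max(0, -sh), L = H - std::abs(sh);
    if (L <= 0) return;
    for (int wo = wlo; wo < whi; wo++) {
      float *y = Y + size_t(H) * wo + hlo;
      const float *pp = P + size_t(H) * (wo + sw) + hlo + sh;
      for (int i = 0; i < L; i++) y[i] += pp[i];
    }
  }
  // Dst(p) = Src(p + (sh, sw)), zero outside
  static void shiftCopy(const float *S, float *D, int H, int W, int sh, int sw) {
    std::fill(D, D + size_t(H) * W, 0.0f);
    int wlo = std::max(0, -sw), whi = std::min(W, W - sw);
    int hlo = std::max(0, -sh), L = H - std::abs(sh);
    if (L <= 0) return;
    for (int wo = wlo; wo < whi; wo++) {
      float *d = D + size_t(H) * wo + hlo;
      const float *sp = S + size_t(H) * (wo + sw) + hlo + sh;
      for (int i = 0; i < L; i++) d[i] = sp[i];
    }
  }

  void forward(const Tensor &x, Tensor &out, bool train) {
    int Ho, Wo; outdims(x.H, x.W, Ho, Wo);
    Hin = x.H; Win = x.W; Nin = x.N;
    out = Tensor(Ho, Wo, cout, x.N);
    size_t HWo = size_t(Ho) * Wo;
    if (direct()) {
      if (Wall.n_elem == 0 || int(Wall.n_rows) != cin) buildWall();
      size_t HW = size_t(x.H) * x.W;
      for (int n = 0; n < x.N; n++) {
        fmat Xn(const_cast<float *>(&x.v[x.idx(0, 0, 0, n)]), HW, cin, false, true);
        fmat Yn(&out.v[out.idx(0, 0, 0, n)], HW, cout, false, true);
        for (int f = 0; f < cout; f++)
          std::fill(Yn.colptr(f), Yn.colptr(f) + HW, b[f]);
        if (k == 1) {
          Yn += Xn * Wall;
        } else {
          Ymat = Xn * Wall;  // HW x (k*k*cout)
          for (int dw = 0; dw < k; dw++)
            for (int dh = 0; dh < k; dh++) {
              int o = dh + k * dw;
              for (int f = 0; f < cout; f++)
                shiftAdd(Ymat.colptr(size_t(o) * cout + f), Yn.colptr(f),
                         x.H, x.W, dh - pad, dw - pad);
            }
        }
      }
    } else {
      im2col(x, col);
      Ymat = col * Wm;
      Ymat.each_row() += b.t();
      for (int f = 0; f < cout; f++) {
        const float *src = Ymat.colptr(f);
        for (int n = 0; n < x.N; n++)
          std::copy(src + HWo * n, src + HWo * (n + 1),
                    &out.v[out.idx(0, 0, f, n)]);
      }
    }
    if (train) {
      zcache = out.v;  // pre-activations in output layout
      if (direct()) xin = x;
    }
    for (size_t i = 0; i < out.v.n_elem; i++) out.v[i] = actfun(out.v[i], act);
  }

  // dy has dims of output; returns dx; sets gW, gb (overwrite)
  void backward(const Tensor &dy, Tensor &dx) {
    int Ho = dy.H, Wo = dy.W;
    size_t HWo = size_t(Ho) * Wo;
    // dPre in output-tensor layout
    fvec dpre(dy.v.n_elem);
    for (size_t i = 0; i < dy.v.n_elem; i++)
      dpre[i] = dy.v[i] * actgrad_pre(zcache[i], act);
    dx = Tensor(Hin, Win, cin, Nin, !direct());
    gW.zeros(size_t(cin) * k * k, cout);
    gb.zeros(cout);
    if (direct()) {
      size_t HW = size_t(Hin) * Win;
      int kk = k * k;
      fmat gWall(cin, size_t(kk) * cout, fill::zeros);
      for (int n = 0; n < Nin; n++) {
        fmat Xn(&xin.v[xin.idx(0, 0, 0, n)], HW, cin, false, true);
        fmat dPn(&dpre[size_t(n) * HW * cout], HW, cout, false, true);
        gb += sum(dPn, 0).t();
        fmat dXn(&dx.v[dx.idx(0, 0, 0, n)], HW, cin, false, true);
        if (k == 1) {
          gWall += Xn.t() * dPn;
          if (needDx) dXn = dPn * Wall.t();
        } else {
          Dsh.set_size(HW, size_t(kk) * cout);
          for (int dw = 0; dw < k; dw++)
            for (int dh = 0; dh < k; dh++) {
              int o = dh + k * dw;
              for (int f = 0; f < cout; f++)
                shiftCopy(dPn.colptr(f), Dsh.colptr(size_t(o) * cout + f),
                          Hin, Win, -(dh - pad), -(dw - pad));
            }
          gWall += Xn.t() * Dsh;
          if (needDx) dXn = Dsh * Wall.t();
        }
      }
      // scatter gWall back into the canonical (C*k*k) x F layout
      for (int c = 0; c < cin; c++)
        for (int o = 0; o < kk; o++)
          for (int f = 0; f < cout; f++)
            gW(size_t(o) + size_t(kk) * c, f) = gWall(c, size_t(o) * cout + f);
    } else {
      dY.set_size(HWo * dy.N, cout);
      for (int f = 0; f < cout; f++) {
        float *dst = dY.colptr(f);
        for (int n = 0; n < dy.N; n++)
          std::copy(&dpre[dy.idx(0, 0, f, n)], &dpre[dy.idx(0, 0, f, n)] + HWo,
                    dst + HWo * n);
      }
      gW = col.t() * dY;
      gb = sum(dY, 0).t();
      if (needDx) {
        dcol = dY * Wm.t();
        col2im(dcol, dx);
      }
    }
  }

  void adam(float lr, float b1, float b2, float eps, int t) {
    float c1 = 1.0f - std::pow(b1, float(t));
    float c2 = 1.0f - std::pow(b2, float(t));
    mW = b1 * mW + (1.0f - b1) * gW;
    vW = b2 * vW + (1.0f - b2) * square(gW);
    Wm -= lr * (mW / c1) / (sqrt(vW / c2) + eps);
    mb = b1 * mb + (1.0f - b1) * gb;
    vb = b2 * vb + (1.0f - b2) * square(gb);
    b -= lr * (mb / c1) / (sqrt(vb / c2) + eps);
    if (Wall.n_elem) buildWall();
  }

  size_t nparams() const { return Wm.n_elem + b.n_elem; }
};

// nearest-neighbour 2x upsampling
static void upsample2(const Tensor &x, Tensor &y) {
  y = Tensor(x.H * 2, x.W * 2, x.C, x.N);
  for (int n = 0; n < x.N; n++)
    for (int c = 0; c < x.C; c++)
      for (int w = 0; w < x.W * 2; w++) {
        const float *src = &x.v[x.idx(0, w / 2, c, n)];
        float *dst = &y.v[y.idx(0, w, c, n)];
        for (int h = 0; h < x.H * 2; h++) dst[h] = src[h / 2];
      }
}
static void upsample2_back(const Tensor &dy, Tensor &dx, int H, int W) {
  dx = Tensor(H, W, dy.C, dy.N, true);
  for (int n = 0; n < dy.N; n++)
    for (int c = 0; c < dy.C; c++)
      for (int w = 0; w < dy.W; w++) {
        const float *src = &dy.v[dy.idx(0, w, c, n)];
        float *dst = &dx.v[dx.idx(0, w / 2, c, n)];
        for (int h = 0; h < dy.H; h++) dst[h / 2] += src[h];
      }
}

static void concatC(const Tensor &a, const Tensor &b, Tensor &y) {
  y = Tensor(a.H, a.W, a.C + b.C, a.N);
  for (int n = 0; n < a.N; n++) {
    std::copy(&a.v[a.idx(0, 0, 0, n)], &a.v[a.idx(0, 0, 0, n)] + size_t(a.H) * a.W * a.C,
              &y.v[y.idx(0, 0, 0, n)]);
    std::copy(&b.v[b.idx(0, 0, 0, n)], &b.v[b.idx(0, 0, 0, n)] + size_t(b.H) * b.W * b.C,
              &y.v[y.idx(0, 0, a.C, n)]);
  }
}
static void splitC(const Tensor &dy, int ca, Tensor &da, Tensor &db) {
  int cb = dy.C - ca;
  da = Tensor(dy.H, dy.W, ca, dy.N);
  db = Tensor(dy.H, dy.W, cb, dy.N);
  for (int n = 0; n < dy.N; n++) {
    std::copy(&dy.v[dy.idx(0, 0, 0, n)], &dy.v[dy.idx(0, 0, 0, n)] + size_t(dy.H) * dy.W * ca,
              &da.v[da.idx(0, 0, 0, n)]);
    std::copy(&dy.v[dy.idx(0, 0, ca, n)], &dy.v[dy.idx(0, 0, ca, n)] + size_t(dy.H) * dy.W * cb,
              &db.v[db.idx(0, 0, 0, n)]);
  }
}

// ---------------------------------------------------------------------------
// Attention gate: skip s gated by decoder signal u (both cf channels).
// psi = sigmoid(conv1(relu(convg(u) + convx(s)))); out = s .* psi
// ---------------------------------------------------------------------------
struct AttentionGate {
  ConvLayer wg, wx, psi;  // all 1x1
  Tensor a_cache, psi_cache, s_cache;

  void build(int cf, std::mt19937 &rng) {
    int fa = std::max(cf / 2, 1);
    wg.k = wx.k = psi.k = 1; wg.pad = wx.pad = psi.pad = 0;
    wg.cin = cf; wg.cout = fa; wg.act = LINEAR; wg.init(rng);
    wx.cin = cf; wx.cout = fa; wx.act = LINEAR; wx.init(rng);
    psi.cin = fa; psi.cout = 1; psi.act = SIGMOID; psi.init(rng);
  }
  void forward(const Tensor &u, const Tensor &s, Tensor &out, bool train) {
    Tensor g1, x1;
    wg.forward(u, g1, train);
    wx.forward(s, x1, train);
    Tensor a = g1;
    for (size_t i = 0; i < a.v.n_elem; i++) {
      float z = g1.v[i] + x1.v[i];
      a.v[i] = z > 0 ? z : 0.0f;
    }
    Tensor p;
    psi.forward(a, p, train);
    out = s;
    for (int n = 0; n < s.N; n++)
      for (int c = 0; c < s.C; c++) {
        const float *pp = &p.v[p.idx(0, 0, 0, n)];
        float *oo = &out.v[out.idx(0, 0, c, n)];
        for (size_t i = 0; i < size_t(s.H) * s.W; i++) oo[i] *= pp[i];
      }
    if (train) { a_cache = std::move(a); psi_cache = std::move(p); s_cache = s; }
  }
  // returns du and ds given d(out)
  void backward(const Tensor &dout, Tensor &du, Tensor &ds) {
    // d psi = sum_c dout .* s ; ds (direct) = dout .* psi
    Tensor dp(psi_cache.H, psi_cache.W, 1, psi_cache.N, true);
    ds = dout;
    for (int n = 0; n < dout.N; n++) {
      float *dpp = &dp.v[dp.idx(0, 0, 0, n)];
      for (int c = 0; c < dout.C; c++) {
        const float *dd = &dout.v[dout.idx(0, 0, c, n)];
        const float *ss = &s_cache.v[s_cache.idx(0, 0, c, n)];
        const float *pp = &psi_cache.v[psi_cache.idx(0, 0, 0, n)];
        float *dss = &ds.v[ds.idx(0, 0, c, n)];
        for (size_t i = 0; i < size_t(dout.H) * dout.W; i++) {
          dpp[i] += dd[i] * ss[i];
          dss[i] = dd[i] * pp[i];
        }
      }
    }
    Tensor da;
    psi.backward(dp, da);
    for (size_t i = 0; i < da.v.n_elem; i++) da.v[i] *= (a_cache.v[i] > 0 ? 1.0f : 0.0f);
    Tensor dsx;
    wg.backward(da, du);
    wx.backward(da, dsx);
    for (size_t i = 0; i < ds.v.n_elem; i++) ds.v[i] += dsx.v[i];
  }
  void adam(float lr, float b1, float b2, float eps, int t) {
    wg.adam(lr, b1, b2, eps, t); wx.adam(lr, b1, b2, eps, t); psi.adam(lr, b1, b2, eps, t);
  }
  size_t nparams() const { return wg.nparams() + wx.nparams() + psi.nparams(); }
};

// ---------------------------------------------------------------------------
// Networks
// ---------------------------------------------------------------------------
struct NetBase {
  int adam_t = 0;
  float b1 = 0.9f, b2 = 0.999f, eps = 1e-8f;
  virtual ~NetBase() {}
  virtual Rcpp::NumericVector forward(const Tensor &x, bool train) = 0;
  virtual Tensor backward(const Rcpp::NumericVector &dy) = 0;
  virtual void step(float lr) = 0;
  virtual Rcpp::List params() const = 0;
  virtual void set_params(const Rcpp::List &p) = 0;
  virtual Rcpp::List grads() const = 0;
  virtual double nparams() const = 0;
};

static Tensor as_tensor(const Rcpp::NumericVector &x) {
  Rcpp::IntegerVector d = x.attr("dim");
  int H = d[0], W = d[1], C = d.size() > 2 ? d[2] : 1, N = d.size() > 3 ? d[3] : 1;
  Tensor t(H, W, C, N);
  for (size_t i = 0; i < t.v.n_elem; i++) t.v[i] = float(x[i]);
  return t;
}
static Rcpp::NumericVector as_array(const Tensor &t) {
  Rcpp::NumericVector out(t.v.n_elem);
  for (size_t i = 0; i < t.v.n_elem; i++) out[i] = t.v[i];
  out.attr("dim") = Rcpp::IntegerVector::create(t.H, t.W, t.C, t.N);
  return out;
}
static Rcpp::NumericMatrix fmat_to_R(const fmat &m) {
  Rcpp::NumericMatrix out(m.n_rows, m.n_cols);
  for (uword j = 0; j < m.n_cols; j++)
    for (uword i = 0; i < m.n_rows; i++) out(i, j) = m(i, j);
  return out;
}
static void R_to_fmat(const Rcpp::NumericMatrix &src, fmat &dst) {
  if (int(dst.n_rows) != src.nrow() || int(dst.n_cols) != src.ncol())
    Rcpp::stop("parameter matrix shape mismatch");
  for (int j = 0; j < src.ncol(); j++)
    for (int i = 0; i < src.nrow(); i++) dst(i, j) = float(src(i, j));
}

struct UNet : NetBase {
  int depth, base, cin, cout, finalAct;
  bool attention;
  std::vector<ConvLayer> enc, down, up, dec;
  ConvLayer bott, outc;
  std::vector<AttentionGate> att;
  // caches
  std::vector<Tensor> skip_cache;
  std::vector<int> updims_H, updims_W;
  std::vector<Tensor> att_u_cache;  // upconv outputs (needed for concat split bookkeeping)

  UNet(int depth_, int base_, int cin_, int cout_, bool attention_, int finalAct_, int seed) {
    depth = depth_; base = base_; cin = cin_; cout = cout_;
    attention = attention_; finalAct = finalAct_;
    std::mt19937 rng(seed);
    enc.resize(depth); down.resize(depth); up.resize(depth); dec.resize(depth);
    if (attention) att.resize(depth);
    int cprev = cin;
    for (int l = 0; l < depth; l++) {
      int cf = base << l;
      enc[l].cin = cprev; enc[l].cout = cf; enc[l].act = RELU; enc[l].init(rng);
      if (l == 0) enc[l].needDx = false;
      down[l].cin = cf; down[l].cout = cf * 2; down[l].stride = 2; down[l].act = RELU; down[l].init(rng);
      cprev = cf * 2;
    }
    bott.cin = cprev; bott.cout = cprev; bott.act = RELU; bott.init(rng);
    for (int l = depth - 1; l >= 0; l--) {
      int cf = base << l;
      up[l].cin = cf * 2; up[l].cout = cf; up[l].act = RELU; up[l].init(rng);
      if (attention) att[l].build(cf, rng);
      dec[l].cin = cf * 2; dec[l].cout = cf; dec[l].act = RELU; dec[l].init(rng);
    }
    outc.k = 1; outc.pad = 0; outc.cin = base; outc.cout = cout; outc.act = finalAct;
    outc.init(rng);
  }

  Rcpp::NumericVector forward(const Tensor &x0, bool train) override {
    int mult = 1 << depth;
    if (x0.H % mult != 0 || x0.W % mult != 0)
      Rcpp::stop("input spatial dims must be a multiple of %d (2^depth)", mult);
    if (x0.C != cin) Rcpp::stop("expected %d input channels, got %d", cin, x0.C);
    skip_cache.assign(depth, Tensor());
    updims_H.assign(depth, 0); updims_W.assign(depth, 0);
    Tensor x = x0, t;
    for (int l = 0; l < depth; l++) {
      enc[l].forward(x, skip_cache[l], train);
      updims_H[l] = skip_cache[l].H; updims_W[l] = skip_cache[l].W;
      down[l].forward(skip_cache[l], x, train);
    }
    bott.forward(x, t, train); x = std::move(t);
    for (int l = depth - 1; l >= 0; l--) {
      Tensor u2;
      upsample2(x, u2);
      Tensor u;
      up[l].forward(u2, u, train); // cf channels at skip resolution
      Tensor sg;
      if (attention) att[l].forward(u, skip_cache[l], sg, train);
      else sg = skip_cache[l];
      Tensor cc;
      concatC(u, sg, cc);
      dec[l].forward(cc, x, train);
    }
    Tensor yout;
    outc.forward(x, yout, train);
    return as_array(yout);
  }

  Tensor backward(const Rcpp::NumericVector &dyR) override {
    Tensor dy = as_tensor(dyR);
    Tensor dx, t;
    outc.backward(dy, dx);
    std::vector<Tensor> dskip(depth);
    for (int l = 0; l < depth; l++) {
      // decoder backward in forward-level order (reverse of execution: level 0 ran last)
      Tensor dcc;
      dec[l].backward(dx, dcc);
      Tensor du, dsg;
      splitC(dcc, up[l].cout, du, dsg);
      Tensor ds;
      if (attention) {
        Tensor du2;
        att[l].backward(dsg, du2, ds);
        for (size_t i = 0; i < du.v.n_elem; i++) du.v[i] += du2.v[i];
      } else ds = dsg;
      dskip[l] = ds;
      Tensor du_pre;
      up[l].backward(du, du_pre);
      upsample2_back(du_pre, dx, du_pre.H / 2, du_pre.W / 2);
    }
    bott.backward(dx, t); dx = std::move(t);
    for (int l = depth - 1; l >= 0; l--) {
      down[l].backward(dx, t); dx = std::move(t);
      for (size_t i = 0; i < dx.v.n_elem; i++) dx.v[i] += dskip[l].v[i];
      enc[l].backward(dx, t); dx = std::move(t);
    }
    return dx;
  }

  void step(float lr) override {
    adam_t++;
    for (int l = 0; l < depth; l++) {
      enc[l].adam(lr, b1, b2, eps, adam_t);
      down[l].adam(lr, b1, b2, eps, adam_t);
      up[l].adam(lr, b1, b2, eps, adam_t);
      dec[l].adam(lr, b1, b2, eps, adam_t);
      if (attention) att[l].adam(lr, b1, b2, eps, adam_t);
    }
    bott.adam(lr, b1, b2, eps, adam_t);
    outc.adam(lr, b1, b2, eps, adam_t);
  }

  void collect(std::vector<std::pair<std::string, const ConvLayer *>> &out) const {
    for (int l = 0; l < depth; l++) {
      out.push_back({"enc" + std::to_string(l), &enc[l]});
      out.push_back({"down" + std::to_string(l), &down[l]});
      out.push_back({"up" + std::to_string(l), &up[l]});
      out.push_back({"dec" + std::to_string(l), &dec[l]});
      if (attention) {
        out.push_back({"att" + std::to_string(l) + "_g", &att[l].wg});
        out.push_back({"att" + std::to_string(l) + "_x", &att[l].wx});
        out.push_back({"att" + std::to_string(l) + "_psi", &att[l].psi});
      }
    }
    out.push_back({"bott", &bott});
    out.push_back({"out", &outc});
  }
  Rcpp::List params() const override {
    std::vector<std::pair<std::string, const ConvLayer *>> ls;
    collect(ls);
    Rcpp::List out;
    for (auto &p : ls) {
      out[p.first + "_W"] = fmat_to_R(p.second->Wm);
      out[p.first + "_b"] = Rcpp::NumericVector(p.second->b.begin(), p.second->b.end());
    }
    return out;
  }
  Rcpp::List grads() const override {
    std::vector<std::pair<std::string, const ConvLayer *>> ls;
    collect(ls);
    Rcpp::List out;
    for (auto &p : ls) {
      out[p.first + "_W"] = fmat_to_R(p.second->gW);
      out[p.first + "_b"] = Rcpp::NumericVector(p.second->gb.begin(), p.second->gb.end());
    }
    return out;
  }
  void set_params(const Rcpp::List &p) override {
    std::vector<std::pair<std::string, const ConvLayer *>> ls;
    collect(ls);
    for (auto &pr : ls) {
      ConvLayer *L = const_cast<ConvLayer *>(pr.second);
      Rcpp::NumericMatrix W = p[pr.first + "_W"];
      R_to_fmat(W, L->Wm);
      Rcpp::NumericVector b = p[pr.first + "_b"];
      if (int(L->b.n_elem) != b.size()) Rcpp::stop("bias shape mismatch");
      for (int i = 0; i < b.size(); i++) L->b[i] = float(b[i]);
      if (L->Wall.n_elem) L->buildWall();
    }
  }
  double nparams() const override {
    std::vector<std::pair<std::string, const ConvLayer *>> ls;
    collect(ls);
    double s = 0;
    for (auto &p : ls) s += double(p.second->nparams());
    return s;
  }
};

// CNN classifier: strided conv stack -> global average pool -> dense -> sigmoid
struct CNNClassifier : NetBase {
  int depth, base, cin;
  std::vector<ConvLayer> convs;
  fmat Wd; float bd = 0;  // dense (clast x 1)
  fmat gWd; float gbd = 0;
  fmat mWd, vWd; float mbd = 0, vbd = 0;
  // caches
  fmat gap_cache;       // clast x N
  Rcpp::NumericVector out_cache;  // sigmoid outputs, length N
  int Hl = 0, Wl = 0;

  CNNClassifier(int depth_, int base_, int cin_, int seed) {
    depth = depth_; base = base_; cin = cin_;
    std::mt19937 rng(seed);
    convs.resize(depth);
    int cprev = cin;
    for (int l = 0; l < depth; l++) {
      int cf = base << l;
      convs[l].cin = cprev; convs[l].cout = cf; convs[l].stride = 2; convs[l].act = LEAKY;
      convs[l].init(rng);
      cprev = cf;
    }
    std::normal_distribution<float> nd(0.0f, std::sqrt(2.0f / float(cprev)));
    Wd.set_size(cprev, 1);
    for (uword i = 0; i < Wd.n_rows; i++) Wd(i, 0) = nd(rng);
    bd = 0;
    gWd.zeros(cprev, 1); mWd.zeros(cprev, 1); vWd.zeros(cprev, 1);
  }

  Rcpp::NumericVector forward(const Tensor &x0, bool train) override {
    if (x0.C != cin) Rcpp::stop("expected %d input channels, got %d", cin, x0.C);
    int mult = 1 << depth;
    if (x0.H % mult != 0 || x0.W % mult != 0)
      Rcpp::stop("input spatial dims must be a multiple of %d (2^depth)", mult);
    Tensor x = x0, t;
    for (int l = 0; l < depth; l++) { convs[l].forward(x, t, train); x = std::move(t); }
    Hl = x.H; Wl = x.W;
    int cl = x.C;
    fmat gap(cl, x.N, fill::zeros);
    for (int n = 0; n < x.N; n++)
      for (int c = 0; c < cl; c++) {
        const float *src = &x.v[x.idx(0, 0, c, n)];
        float s = 0;
        for (size_t i = 0; i < size_t(x.H) * x.W; i++) s += src[i];
        gap(c, n) = s / float(x.H * x.W);
      }
    Rcpp::NumericVector out(x.N);
    for (int n = 0; n < x.N; n++) {
      float z = dot(gap.col(n), Wd.col(0)) + bd;
      out[n] = 1.0 / (1.0 + std::exp(-double(z)));
    }
    if (train) { gap_cache = gap; out_cache = out; }
    return out;
  }

  Tensor backward(const Rcpp::NumericVector &dy) override {
    int N = dy.size();
    int cl = gap_cache.n_rows;
    fvec dz(N);
    for (int n = 0; n < N; n++) {
      double o = out_cache[n];
      dz[n] = float(dy[n] * o * (1.0 - o));
    }
    gWd.zeros(cl, 1); gbd = 0;
    fmat dgap(cl, N);
    for (int n = 0; n < N; n++) {
      gWd.col(0) += dz[n] * gap_cache.col(n);
      gbd += dz[n];
      dgap.col(n) = dz[n] * Wd.col(0);
    }
    Tensor dx(Hl, Wl, cl, N);  // fully overwritten below
    float inv = 1.0f / float(Hl * Wl);
    for (int n = 0; n < N; n++)
      for (int c = 0; c < cl; c++) {
        float g = dgap(c, n) * inv;
        float *dst = &dx.v[dx.idx(0, 0, c, n)];
        for (size_t i = 0; i < size_t(Hl) * Wl; i++) dst[i] = g;
      }
    Tensor t;
    for (int l = depth - 1; l >= 0; l--) { convs[l].backward(dx, t); dx = std::move(t); }
    return dx;
  }

  void step(float lr) override {
    adam_t++;
    for (int l = 0; l < depth; l++) convs[l].adam(lr, b1, b2, eps, adam_t);
    float c1 = 1.0f - std::pow(b1, float(adam_t));
    float c2 = 1.0f - std::pow(b2, float(adam_t));
    mWd = b1 * mWd + (1 - b1) * gWd;
    vWd = b2 * vWd + (1 - b2) * square(gWd);
    Wd -= lr * (mWd / c1) / (sqrt(vWd / c2) + eps);
    mbd = b1 * mbd + (1 - b1) * gbd;
    vbd = b2 * vbd + (1 - b2) * gbd * gbd;
    bd -= lr * (mbd / c1) / (std::sqrt(vbd / c2) + eps);
  }

  Rcpp::List params() const override {
    Rcpp::List out;
    for (int l = 0; l < depth; l++) {
      out["conv" + std::to_string(l) + "_W"] = fmat_to_R(convs[l].Wm);
      out["conv" + std::to_string(l) + "_b"] =
          Rcpp::NumericVector(convs[l].b.begin(), convs[l].b.end());
    }
    out["dense_W"] = fmat_to_R(Wd);
    out["dense_b"] = Rcpp::NumericVector::create(bd);
    return out;
  }
  Rcpp::List grads() const override {
    Rcpp::List out;
    for (int l = 0; l < depth; l++) {
      out["conv" + std::to_string(l) + "_W"] = fmat_to_R(convs[l].gW);
      out["conv" + std::to_string(l) + "_b"] =
          Rcpp::NumericVector(convs[l].gb.begin(), convs[l].gb.end());
    }
    out["dense_W"] = fmat_to_R(gWd);
    out["dense_b"] = Rcpp::NumericVector::create(gbd);
    return out;
  }
  void set_params(const Rcpp::List &p) override {
    for (int l = 0; l < depth; l++) {
      Rcpp::NumericMatrix W = p["conv" + std::to_string(l) + "_W"];
      R_to_fmat(W, convs[l].Wm);
      Rcpp::NumericVector b = p["conv" + std::to_string(l) + "_b"];
      for (int i = 0; i < b.size(); i++) convs[l].b[i] = float(b[i]);
      if (convs[l].Wall.n_elem) convs[l].buildWall();
    }
    Rcpp::NumericMatrix W = p["dense_W"];
    R_to_fmat(W, Wd);
    Rcpp::NumericVector b = p["dense_b"];
    bd = float(b[0]);
  }
  double nparams() const override {
    double s = 0;
    for (int l = 0; l < depth; l++) s += double(convs[l].nparams());
    return s + Wd.n_elem + 1;
  }
};

// ---------------------------------------------------------------------------
// Exported interface
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
SEXP net_create(std::string type, int depth, int base, int cin, int cout,
                bool attention, std::string final_act, int seed) {
  if (depth < 1) Rcpp::stop("depth must be >= 1");
  if (base < 1 || cin < 1 || cout < 1) Rcpp::stop("channel counts must be positive");
  int fa = final_act == "sigmoid" ? SIGMOID : LINEAR;
  NetBase *net;
  if (type == "unet") net = new UNet(depth, base, cin, cout, attention, fa, seed);
  else if (type == "cnn") net = new CNNClassifier(depth, base, cin, seed);
  else Rcpp::stop("unknown network type '%s'", type.c_str());
  Rcpp::XPtr<NetBase> ptr(net, true);
  return ptr;
}

// [[Rcpp::export]]
Rcpp::NumericVector net_forward(SEXP netp, Rcpp::NumericVector x, bool train = true) {
  Rcpp::XPtr<NetBase> net(netp);
  return net->forward(as_tensor(x), train);
}

// [[Rcpp::export]]
Rcpp::NumericVector net_backward(SEXP netp, Rcpp::NumericVector dy) {
  Rcpp::XPtr<NetBase> net(netp);
  return as_array(net->backward(dy));
}

// [[Rcpp::export]]
void net_step(SEXP netp, double lr) {
  Rcpp::XPtr<NetBase> net(netp);
  net->step(float(lr));
}

// [[Rcpp::export]]
Rcpp::List net_params(SEXP netp) {
  Rcpp::XPtr<NetBase> net(netp);
  return net->params();
}

// [[Rcpp::export]]
void net_set_params(SEXP netp, Rcpp::List p) {
  Rcpp::XPtr<NetBase> net(netp);
  net->set_params(p);
}

// [[Rcpp::export]]
Rcpp::List net_grads(SEXP netp) {
  Rcpp::XPtr<NetBase> net(netp);
  return net->grads();
}

// [[Rcpp::export]]
double net_nparams(SEXP netp) {
  Rcpp::XPtr<NetBase> net(netp);
  return net->nparams();
}

// ---------------------------------------------------------------------------
// 8-connected component labeling (EBImage::bwlabel is 4-connected)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
Rcpp::IntegerMatrix label_components8(Rcpp::NumericMatrix mask) {
  int H = mask.nrow(), W = mask.ncol();
  Rcpp::IntegerMatrix lab(H, W);
  int next = 0;
  std::vector<std::pair<int, int>> stack;
  for (int w = 0; w < W; w++)
    for (int h = 0; h < H; h++) {
      if (mask(h, w) == 0 || lab(h, w) != 0) continue;
      next++;
      stack.push_back({h, w});
      lab(h, w) = next;
      while (!stack.empty()) {
        auto pq = stack.back(); stack.pop_back();
        for (int dw = -1; dw <= 1; dw++)
          for (int dh = -1; dh <= 1; dh++) {
            int nh = pq.first + dh, nw = pq.second + dw;
            if (nh < 0 || nh >= H || nw < 0 || nw >= W) continue;
            if (mask(nh, nw) != 0 && lab(nh, nw) == 0) {
              lab(nh, nw) = next;
              stack.push_back({nh, nw});
            }
          }
      }
    }
  return lab;
}

// ---------------------------------------------------------------------------
// Bilinear warp forward (border replication) and windowed-NCC gradient,
// mirrored from the reference R implementations for the training hot path.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
Rcpp::NumericVector warp_bilinear(Rcpp::NumericVector img, Rcpp::NumericMatrix dx,
                                  Rcpp::NumericMatrix dy) {
  Rcpp::IntegerVector d = img.attr("dim");
  int H = d[0], W = d[1], C = d.size() > 2 ? d[2] : 1;
  Rcpp::NumericVector out(img.size());
  out.attr("dim") = img.attr("dim");
  std::vector<int> k00(size_t(H) * W), k01(size_t(H) * W), k10(size_t(H) * W),
      k11(size_t(H) * W);
  std::vector<double> wx(size_t(H) * W), wy(size_t(H) * W);
  for (int w = 0; w < W; w++)
    for (int h = 0; h < H; h++) {
      size_t i = size_t(h) + size_t(H) * w;
      double xs = (w + 1) + dx(h, w);
      double ys = (h + 1) + dy(h, w);
      xs = std::min(std::max(xs, 1.0), double(W));
      ys = std::min(std::max(ys, 1.0), double(H));
      int x0 = int(std::floor(xs)); if (x0 > W - 1) x0 = W - 1; if (x0 < 1) x0 = 1;
      int y0 = int(std::floor(ys)); if (y0 > H - 1) y0 = H - 1; if (y0 < 1) y0 = 1;
      int x1 = std::min(x0 + 1, W), y1 = std::min(y0 + 1, H);
      wx[i] = xs - x0; wy[i] = ys - y0;
      k00[i] = (y0 - 1) + H * (x0 - 1);
      k01[i] = (y0 - 1) + H * (x1 - 1);
      k10[i] = (y1 - 1) + H * (x0 - 1);
      k11[i] = (y1 - 1) + H * (x1 - 1);
    }
  for (int c = 0; c < C; c++) {
    const double *p = &img[size_t(H) * W * c];
    double *o = &out[size_t(H) * W * c];
    for (size_t i = 0; i < size_t(H) * W; i++) {
      double a = (1 - wy[i]) * ((1 - wx[i]) * p[k00[i]] + wx[i] * p[k01[i]]);
      double b = wy[i] * ((1 - wx[i]) * p[k10[i]] + wx[i] * p[k11[i]]);
      o[i] = a + b;
    }
  }
  return out;
}

// gradient of the mean windowed Pearson correlation w.r.t. the second image
// [[Rcpp::export]]
Rcpp::NumericVector ncc_grad_b(Rcpp::NumericVector a, Rcpp::NumericVector b,
                               int k, int stride, double eps) {
  Rcpp::IntegerVector d = a.attr("dim");
  int H = d[0], W = d[1], C = d.size() > 2 ? d[2] : 1;
  Rcpp::NumericVector g(a.size());
  g.attr("dim") = a.attr("dim");
  int ni = (H - k) / stride + 1, nj = (W - k) / stride + 1;
  double nw = double(ni) * nj * C;
  double k2 = double(k) * k;
  for (int c = 0; c < C; c++) {
    const double *pa = &a[size_t(H) * W * c];
    const double *pb = &b[size_t(H) * W * c];
    double *pg = &g[size_t(H) * W * c];
    for (int jj = 0; jj < nj; jj++)
      for (int ii = 0; ii < ni; ii++) {
        int i0 = ii * stride, j0 = jj * stride;
        double sa = 0, sb = 0, saa = 0, sbb = 0, sab = 0;
        for (int x = j0; x < j0 + k; x++)
          for (int y = i0; y < i0 + k; y++) {
            double va = pa[y + size_t(H) * x], vb = pb[y + size_t(H) * x];
            sa += va; sb += vb; saa += va * va; sbb += vb * vb; sab += va * vb;
          }
        double mua = sa / k2, mub = sb / k2;
        double vva = std::max(saa / k2 - mua * mua, 0.0);
        double vvb = std::max(sbb / k2 - mub * mub, 0.0);
        double sda = std::sqrt(vva), sdb = std::sqrt(vvb);
        double den = sda * sdb + eps;
        if (den <= eps && sdb == 0) continue;
        double corr = (sab / k2 - mua * mub) / den;
        double f1 = 1.0 / (k2 * den);
        double f2 = corr * sda / (k2 * std::max(sdb, 1e-12) * den);
        for (int x = j0; x < j0 + k; x++)
          for (int y = i0; y < i0 + k; y++) {
            size_t idx = y + size_t(H) * x;
            pg[idx] += f1 * (pa[idx] - mua) - f2 * (pb[idx] - mub);
          }
      }
  }
  for (size_t i = 0; i < size_t(g.size()); i++) g[i] /= nw;
  return g;
}

// anisotropic TV subgradient (interior differences), (H, W, C) double array
// [[Rcpp::export]]
Rcpp::NumericVector tv_grad(Rcpp::NumericVector a) {
  Rcpp::IntegerVector d = a.attr("dim");
  int H = d[0], W = d[1], C = d.size() > 2 ? d[2] : 1;
  Rcpp::NumericVector g(a.size());
  g.attr("dim") = a.attr("dim");
  for (int c = 0; c < C; c++) {
    const double *p = &a[size_t(H) * W * c];
    double *pg = &g[size_t(H) * W * c];
    for (int w = 0; w < W; w++) {
      size_t o = size_t(H) * w;
      for (int h = 0; h + 1 < H; h++) {
        double s = p[o + h + 1] > p[o + h] ? 1.0 : (p[o + h + 1] < p[o + h] ? -1.0 : 0.0);
        pg[o + h + 1] += s; pg[o + h] -= s;
      }
    }
    for (int w = 0; w + 1 < W; w++) {
      size_t o = size_t(H) * w;
      for (int h = 0; h < H; h++) {
        double s = p[o + H + h] > p[o + h] ? 1.0 : (p[o + H + h] < p[o + h] ? -1.0 : 0.0);
        pg[o + H + h] += s; pg[o + h] -= s;
      }
    }
  }
  return g;
}

// BerHu subgradient and value in one pass
// [[Rcpp::export]]
Rcpp::List berhu_val_grad(Rcpp::NumericVector a, Rcpp::NumericVector b,
                          double delta) {
  Rcpp::NumericVector g(a.size());
  g.attr("dim") = a.attr("dim");
  double val = 0;
  for (R_xlen_t i = 0; i < a.size(); i++) {
    double dv = a[i] - b[i], ad = std::fabs(dv);
    if (ad <= delta) {
      val += ad;
      g[i] = dv > 0 ? 1.0 : (dv < 0 ? -1.0 : 0.0);
    } else {
      val += (dv * dv + delta * delta) / (2 * delta);
      g[i] = dv / delta;
    }
  }
  return Rcpp::List::create(Rcpp::Named("value") = val, Rcpp::Named("grad") = g);
}
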