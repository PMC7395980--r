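// Six-branch multi-view secondary-input residual (MV-SIR) voxel classifier.
//
// Feature maps are stored channels-first as float matrices of size
// C x (H*W*N): column j = n*H*W + x*H + y holds the C-vector of channels at
// spatial position (y, x) of sample n. Convolutions are computed as GEMMs on
// im2col matrices; everything runs in single precision on the BLAS R links.

#include <RcppArmadillo.h>
#include <map>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::fmat;
using arma::fvec;
using arma::uword;
typedef arma::Mat<arma::u32> u32mat;

enum Variant { MV_SIR = 0, MV_I_CNN = 1, MV_CNN = 2 };

struct NetCfg {
  int patch, stem, c4, fc, fusion;
  int rb1_w1, rb1_w2, rb2_w1, rb2_w2;
  Variant variant;
};

static NetCfg parse_cfg(const List& cfg) {
  NetCfg c;
  c.patch = as<int>(cfg["patch_size"]);
  c.stem = as<int>(cfg["stem_channels"]);
  IntegerVector r1 = cfg["rb1_widths"], r2 = cfg["rb2_widths"];
  c.rb1_w1 = r1[0]; c.rb1_w2 = r1[1];
  c.rb2_w1 = r2[0]; c.rb2_w2 = r2[1];
  c.c4 = as<int>(cfg["c4_channels"]);
  c.fc = as<int>(cfg["fc_width"]);
  c.fusion = as<int>(cfg["fusion_width"]);
  std::string v = as<std::string>(cfg["variant"]);
  if (v == "MV-SIR") c.variant = MV_SIR;
  else if (v == "MV-I-CNN") c.variant = MV_I_CNN;
  else if (v == "MV-CNN") c.variant = MV_CNN;
  else stop("unknown variant '%s'", v.c_str());
  return c;
}

typedef std::map<std::string, fmat> ParamMap;

static ParamMap weights_in(const List& w) {
  ParamMap m;
  CharacterVector nm = w.names();
  for (int i = 0; i < w.size(); ++i) {
    NumericMatrix x = w[i];
    arma::mat d(x.begin(), x.nrow(), x.ncol(), false);
    m[as<std::string>(nm[i])] = arma::conv_to<fmat>::from(d);
  }
  return m;
}

static List weights_out(const ParamMap& m) {
  List out;
  CharacterVector nm;
  for (std::map<std::string, fmat>::const_iterator it = m.begin();
       it != m.end(); ++it) {
    arma::mat d = arma::conv_to<arma::mat>::from(it->second);
    out.push_back(wrap(d));
    nm.push_back(it->first);
  }
  out.names() = nm;
  return out;
}

// ---- conv / pool primitives ------------------------------------------------

static fmat im2col3(const fmat& A, int H, int W, int N) {
  const int C = A.n_rows, HW = H * W;
  fmat col(9 * C, (uword)HW * N);
  for (int n = 0; n < N; ++n)
    for (int x = 0; x < W; ++x)
      for (int y = 0; y < H; ++y) {
        const uword j = (uword)n * HW + (uword)x * H + y;
        float* dst = col.colptr(j);
        int o = 0;
        for (int dx = -1; dx <= 1; ++dx)
          for (int dy = -1; dy <= 1; ++dy, ++o) {
            const int yy = y + dy, xx = x + dx;
            if (yy >= 0 && yy < H && xx >= 0 && xx < W)
              std::memcpy(dst + (size_t)o * C,
                          A.colptr((uword)n * HW + (uword)xx * H + yy),
                          C * sizeof(float));
            else
              std::memset(dst + (size_t)o * C, 0, C * sizeof(float));
          }
      }
  return col;
}

static fmat col2im3(const fmat& dcol, int C, int H, int W, int N) {
  const int HW = H * W;
  fmat dA(C, (uword)HW * N, arma::fill::zeros);
  for (int n = 0; n < N; ++n)
    for (int x = 0; x < W; ++x)
      for (int y = 0; y < H; ++y) {
        const uword j = (uword)n * HW + (uword)x * H + y;
        const float* src = dcol.colptr(j);
        int o = 0;
        for (int dx = -1; dx <= 1; ++dx)
          for (int dy = -1; dy <= 1; ++dy, ++o) {
            const int yy = y + dy, xx = x + dx;
            if (yy >= 0 && yy < H && xx >= 0 && xx < W) {
              float* dst = dA.colptr((uword)n * HW + (uword)xx * H + yy);
              const float* s = src + (size_t)o * C;
              for (int c = 0; c < C; ++c) dst[c] += s[c];
            }
          }
      }
  return dA;
}

// fused bias-add (and optional ReLU) in one pass
static void bias_relu_(fmat& A, const fmat& b, bool relu) {
  const uword C = A.n_rows;
  const float* bp = b.memptr();
  for (uword j = 0; j < A.n_cols; ++j) {
    float* a = A.colptr(j);
    if (relu)
      for (uword c = 0; c < C; ++c) { float v = a[c] + bp[c]; a[c] = v > 0.f ? v : 0.f; }
    else
      for (uword c = 0; c < C; ++c) a[c] += bp[c];
  }
}

static void relu_(fmat& A) {
  float* p = A.memptr();
  for (uword i = 0; i < A.n_elem; ++i) if (p[i] < 0.f) p[i] = 0.f;
}

// 3x3 same-padded convolution
static fmat conv3_fwd(const fmat& A, const fmat& W, const fmat& b,
                      int H, int Wd, int N, bool relu) {
  fmat out = W.t() * im2col3(A, H, Wd, N);
  bias_relu_(out, b, relu);
  return out;
}

// 1x1 convolution (plain channel mix)
static fmat conv1_fwd(const fmat& A, const fmat& W, const fmat& b, bool relu) {
  fmat out = W.t() * A;
  bias_relu_(out, b, relu);
  return out;
}

struct Pooled { fmat out; u32mat src; };

// 2x2 max pooling; stride 2 with ceil-mode output, or stride 1 "same".
// src (argmax bookkeeping for backward) is filled only when want_src.
static Pooled pool2_fwd(const fmat& A, int H, int W, int N, int stride,
                        bool want_src) {
  const int C = A.n_rows, HW = H * W;
  const int Ho = (stride == 1) ? H : (H + 1) / 2;
  const int Wo = (stride == 1) ? W : (W + 1) / 2;
  Pooled P;
  P.out.set_size(C, (uword)Ho * Wo * N);
  if (want_src) P.src.set_size(C, (uword)Ho * Wo * N);
  for (int n = 0; n < N; ++n)
    for (int xo = 0; xo < Wo; ++xo)
      for (int yo = 0; yo < Ho; ++yo) {
        const uword j = (uword)n * Ho * Wo + (uword)xo * Ho + yo;
        const int y0 = yo * stride, x0 = xo * stride;
        float* out = P.out.colptr(j);
        arma::u32* src = want_src ? P.src.colptr(j) : nullptr;
        bool first = true;
        for (int xx = x0; xx < std::min(x0 + 2, W); ++xx)
          for (int yy = y0; yy < std::min(y0 + 2, H); ++yy) {
            const uword jc = (uword)n * HW + (uword)xx * H + yy;
            const float* a = A.colptr(jc);
            if (first) {
              if (want_src)
                for (int c = 0; c < C; ++c) { out[c] = a[c]; src[c] = (arma::u32)jc; }
              else
                std::memcpy(out, a, C * sizeof(float));
              first = false;
            } else {
              if (want_src) {
                for (int c = 0; c < C; ++c)
                  if (a[c] > out[c]) { out[c] = a[c]; src[c] = (arma::u32)jc; }
              } else {
                for (int c = 0; c < C; ++c) if (a[c] > out[c]) out[c] = a[c];
              }
            }
          }
      }
  return P;
}

static fmat pool2_bwd(const fmat& dOut, const u32mat& src, uword ncol_in) {
  fmat dA(dOut.n_rows, ncol_in, arma::fill::zeros);
  for (uword j = 0; j < dOut.n_cols; ++j) {
    const float* g = dOut.colptr(j);
    const arma::u32* s = src.colptr(j);
    for (uword c = 0; c < dOut.n_rows; ++c) dA(c, s[c]) += g[c];
  }
  return dA;
}

// (C x HW*N) -> (C*HW x N), feature index = pos*C + c
static fmat flatten(const fmat& A, int HW, int N) {
  const int C = A.n_rows;
  fmat F((uword)C * HW, N);
  for (int n = 0; n < N; ++n)
    for (int pos = 0; pos < HW; ++pos)
      std::memcpy(F.colptr(n) + (size_t)pos * C, A.colptr((uword)n * HW + pos),
                  C * sizeof(float));
  return F;
}

static fmat unflatten(const fmat& F, int C, int HW, int N) {
  fmat A(C, (uword)HW * N);
  for (int n = 0; n < N; ++n)
    for (int pos = 0; pos < HW; ++pos)
      std::memcpy(A.colptr((uword)n * HW + pos), F.colptr(n) + (size_t)pos * C,
                  C * sizeof(float));
  return A;
}

static fmat relu_mask_mul(const fmat& grad, const fmat& out) {
  fmat g = grad;
  for (uword i = 0; i < g.n_elem; ++i) if (out(i) <= 0.f) g(i) = 0.f;
  return g;
}

// ---- SIR submodel ----------------------------------------------------------

struct SubCache {
  fmat in;                       // 1 x (P*P*N) primary (= secondary) patch
  fmat a1, p2;  u32mat p2s;
  fmat r1a, r1b, r1out;          // residual block 1 (MV-SIR / MV-I-CNN)
  fmat pb1;                      // plain block 1 (MV-CNN)
  fmat e1, ep2; u32mat ep2s;     // secondary path (MV-SIR)
  fmat cat;                      // input to P3
  fmat p3;  u32mat p3s;
  fmat c4;
  fmat r2a, r2b, r2out, pb2;
  fmat p5;  u32mat p5s;
  fmat f7, f8;
  int H0, H1, H2, N;
};

static std::string pn(int s, const char* name) {
  return "s" + std::to_string(s + 1) + "_" + std::string(name);
}

static const fmat& P(const ParamMap& w, const std::string& key) {
  ParamMap::const_iterator it = w.find(key);
  if (it == w.end()) stop("missing weight '%s'", key.c_str());
  return it->second;
}

static fmat sub_forward(const ParamMap& w, const NetCfg& cfg, int s,
                        const fmat& X, int N, SubCache* cache) {
  const int H0 = cfg.patch, H1 = (H0 + 1) / 2, H2 = (H1 + 1) / 2;
  SubCache local;
  SubCache& C = cache ? *cache : local;
  C.H0 = H0; C.H1 = H1; C.H2 = H2; C.N = N;
  C.in = X;  // 1 x H0*H0*N
  C.a1 = conv3_fwd(C.in, P(w, pn(s, "c1_w")), P(w, pn(s, "c1_b")), H0, H0, N, true);
  Pooled p2 = pool2_fwd(C.a1, H0, H0, N, 2, cache != nullptr);
  C.p2 = p2.out; C.p2s = p2.src;

  fmat block1;
  if (cfg.variant == MV_CNN) {
    C.pb1 = conv3_fwd(C.p2, P(w, pn(s, "pb1_w")), P(w, pn(s, "pb1_b")), H1, H1, N, true);
    block1 = C.pb1;
  } else {
    C.r1a = conv1_fwd(C.p2, P(w, pn(s, "rb1_w1")), P(w, pn(s, "rb1_b1")), true);
    C.r1b = conv3_fwd(C.r1a, P(w, pn(s, "rb1_w2")), P(w, pn(s, "rb1_b2")), H1, H1, N, true);
    fmat main = conv1_fwd(C.r1b, P(w, pn(s, "rb1_w3")), P(w, pn(s, "rb1_b3")), false);
    main += C.p2;                // identity shortcut
    relu_(main);
    C.r1out = main;
    block1 = C.r1out;
  }

  if (cfg.variant == MV_SIR) {
    C.e1 = conv3_fwd(C.in, P(w, pn(s, "ec1_w")), P(w, pn(s, "ec1_b")), H0, H0, N, true);
    Pooled ep2 = pool2_fwd(C.e1, H0, H0, N, 2, cache != nullptr);
    C.ep2 = ep2.out; C.ep2s = ep2.src;
    C.cat = arma::join_cols(block1, C.ep2);
  } else {
    C.cat = block1;
  }

  Pooled p3 = pool2_fwd(C.cat, H1, H1, N, 2, cache != nullptr);
  C.p3 = p3.out; C.p3s = p3.src;
  C.c4 = conv3_fwd(C.p3, P(w, pn(s, "c4_w")), P(w, pn(s, "c4_b")), H2, H2, N, true);

  fmat block2;
  if (cfg.variant == MV_CNN) {
    C.pb2 = conv3_fwd(C.c4, P(w, pn(s, "pb2_w")), P(w, pn(s, "pb2_b")), H2, H2, N, true);
    block2 = C.pb2;
  } else {
    C.r2a = conv1_fwd(C.c4, P(w, pn(s, "rb2_w1")), P(w, pn(s, "rb2_b1")), true);
    C.r2b = conv3_fwd(C.r2a, P(w, pn(s, "rb2_w2")), P(w, pn(s, "rb2_b2")), H2, H2, N, true);
    fmat main = conv1_fwd(C.r2b, P(w, pn(s, "rb2_w3")), P(w, pn(s, "rb2_b3")), false);
    main += C.c4;
    relu_(main);
    C.r2out = main;
    block2 = C.r2out;
  }

  Pooled p5 = pool2_fwd(block2, H2, H2, N, 1, cache != nullptr);  // shape-preserving pool
  C.p5 = p5.out; C.p5s = p5.src;

  fmat flat = flatten(C.p5, H2 * H2, N);
  C.f7 = P(w, pn(s, "f7_w")).t() * flat; bias_relu_(C.f7, P(w, pn(s, "f7_b")), true);
  C.f8 = P(w, pn(s, "f8_w")).t() * C.f7; bias_relu_(C.f8, P(w, pn(s, "f8_b")), true);
  return C.f8;
}

static void acc_grad(ParamMap& g, const std::string& key, const fmat& val) {
  ParamMap::iterator it = g.find(key);
  if (it == g.end()) g[key] = val; else it->second += val;
}

// backward through one submodel; accumulates weight grads into g
static void sub_backward(const ParamMap& w, ParamMap& g, const NetCfg& cfg,
                         int s, const SubCache& C, const fmat& dF8) {
  const int H0 = C.H0, H1 = C.H1, H2 = C.H2, N = C.N;
  fmat d8 = relu_mask_mul(dF8, C.f8);
  acc_grad(g, pn(s, "f8_w"), C.f7 * d8.t());
  acc_grad(g, pn(s, "f8_b"), arma::sum(d8, 1));
  fmat d7 = relu_mask_mul(P(w, pn(s, "f8_w")) * d8, C.f7);
  fmat flat = flatten(C.p5, H2 * H2, N);
  acc_grad(g, pn(s, "f7_w"), flat * d7.t());
  acc_grad(g, pn(s, "f7_b"), arma::sum(d7, 1));
  fmat dFlat = P(w, pn(s, "f7_w")) * d7;
  fmat dP5 = unflatten(dFlat, cfg.c4, H2 * H2, N);
  fmat dBlock2 = pool2_bwd(dP5, C.p5s, (uword)H2 * H2 * N);

  fmat dC4;
  if (cfg.variant == MV_CNN) {
    fmat d = relu_mask_mul(dBlock2, C.pb2);
    acc_grad(g, pn(s, "pb2_w"), im2col3(C.c4, H2, H2, N) * d.t());
    acc_grad(g, pn(s, "pb2_b"), arma::sum(d, 1));
    dC4 = col2im3(P(w, pn(s, "pb2_w")) * d, cfg.c4, H2, H2, N);
  } else {
    fmat dSum = relu_mask_mul(dBlock2, C.r2out);
    // main path: conv1 (linear) <- conv3 (relu) <- conv1 (relu)
    acc_grad(g, pn(s, "rb2_w3"), C.r2b * dSum.t());
    acc_grad(g, pn(s, "rb2_b3"), arma::sum(dSum, 1));
    fmat d2b = relu_mask_mul(P(w, pn(s, "rb2_w3")) * dSum, C.r2b);
    acc_grad(g, pn(s, "rb2_w2"), im2col3(C.r2a, H2, H2, N) * d2b.t());
    acc_grad(g, pn(s, "rb2_b2"), arma::sum(d2b, 1));
    fmat d2a = relu_mask_mul(col2im3(P(w, pn(s, "rb2_w2")) * d2b, cfg.rb2_w1, H2, H2, N), C.r2a);
    acc_grad(g, pn(s, "rb2_w1"), C.c4 * d2a.t());
    acc_grad(g, pn(s, "rb2_b1"), arma::sum(d2a, 1));
    dC4 = P(w, pn(s, "rb2_w1")) * d2a + dSum;   // main + shortcut
  }

  fmat dc4 = relu_mask_mul(dC4, C.c4);
  acc_grad(g, pn(s, "c4_w"), im2col3(C.p3, H2, H2, N) * dc4.t());
  acc_grad(g, pn(s, "c4_b"), arma::sum(dc4, 1));
  const int Cmid = C.cat.n_rows;
  fmat dP3 = col2im3(P(w, pn(s, "c4_w")) * dc4, Cmid, H2, H2, N);
  fmat dCat = pool2_bwd(dP3, C.p3s, (uword)H1 * H1 * N);

  fmat dBlock1, dEp2;
  if (cfg.variant == MV_SIR) {
    dBlock1 = dCat.rows(0, cfg.stem - 1);
    dEp2 = dCat.rows(cfg.stem, 2 * cfg.stem - 1);
    fmat dE1 = pool2_bwd(dEp2, C.ep2s, (uword)H0 * H0 * N);
    fmat de1 = relu_mask_mul(dE1, C.e1);
    acc_grad(g, pn(s, "ec1_w"), im2col3(C.in, H0, H0, N) * de1.t());
    acc_grad(g, pn(s, "ec1_b"), arma::sum(de1, 1));
  } else {
    dBlock1 = dCat;
  }

  fmat dP2;
  if (cfg.variant == MV_CNN) {
    fmat d = relu_mask_mul(dBlock1, C.pb1);
    acc_grad(g, pn(s, "pb1_w"), im2col3(C.p2, H1, H1, N) * d.t());
    acc_grad(g, pn(s, "pb1_b"), arma::sum(d, 1));
    dP2 = col2im3(P(w, pn(s, "pb1_w")) * d, cfg.stem, H1, H1, N);
  } else {
    fmat dSum = relu_mask_mul(dBlock1, C.r1out);
    acc_grad(g, pn(s, "rb1_w3"), C.r1b * dSum.t());
    acc_grad(g, pn(s, "rb1_b3"), arma::sum(dSum, 1));
    fmat d1b = relu_mask_mul(P(w, pn(s, "rb1_w3")) * dSum, C.r1b);
    acc_grad(g, pn(s, "rb1_w2"), im2col3(C.r1a, H1, H1, N) * d1b.t());
    acc_grad(g, pn(s, "rb1_b2"), arma::sum(d1b, 1));
    fmat d1a = relu_mask_mul(col2im3(P(w, pn(s, "rb1_w2")) * d1b, cfg.rb1_w1, H1, H1, N), C.r1a);
    acc_grad(g, pn(s, "rb1_w1"), C.p2 * d1a.t());
    acc_grad(g, pn(s, "rb1_b1"), arma::sum(d1a, 1));
    dP2 = P(w, pn(s, "rb1_w1")) * d1a + dSum;
  }

  fmat dA1 = pool2_bwd(dP2, C.p2s, (uword)H0 * H0 * N);
  fmat da1 = relu_mask_mul(dA1, C.a1);
  acc_grad(g, pn(s, "c1_w"), im2col3(C.in, H0, H0, N) * da1.t());
  acc_grad(g, pn(s, "c1_b"), arma::sum(da1, 1));
  // input gradient not needed
}

// ---- fusion head -----------------------------------------------------------

struct HeadCache { fmat cat6, fu, z, p; };

static fmat head_forward(const ParamMap& w, const fmat f8s[6], HeadCache* hc) {
  HeadCache local;
  HeadCache& H = hc ? *hc : local;
  H.cat6 = arma::join_cols(arma::join_cols(arma::join_cols(f8s[0], f8s[1]),
                                           arma::join_cols(f8s[2], f8s[3])),
                           arma::join_cols(f8s[4], f8s[5]));
  H.fu = P(w, "fu_w").t() * H.cat6; bias_relu_(H.fu, P(w, "fu_b"), true);
  H.z = P(w, "out_w").t() * H.fu; bias_relu_(H.z, P(w, "out_b"), false);
  H.p = 1.0f / (1.0f + arma::exp(-H.z));
  return H.p;
}

// dZ -> grads of head + the six dF8 matrices
static void head_backward(const ParamMap& w, ParamMap& g, const HeadCache& H,
                          const fmat& dZ, int fc, fmat dF8s[6]) {
  acc_grad(g, "out_w", H.fu * dZ.t());
  acc_grad(g, "out_b", arma::sum(dZ, 1));
  fmat dFu = relu_mask_mul(P(w, "out_w") * dZ, H.fu);
  acc_grad(g, "fu_w", H.cat6 * dFu.t());
  acc_grad(g, "fu_b", arma::sum(dFu, 1));
  fmat dCat = P(w, "fu_w") * dFu;
  for (int s = 0; s < 6; ++s) dF8s[s] = dCat.rows((uword)s * fc, (uword)(s + 1) * fc - 1);
}

// ---- exported: forward / predict ------------------------------------------

// each stream arrives as a (patch_pixels x n) double matrix; keep as float
static std::vector<fmat> streams_in(const List& streams) {
  if (streams.size() != 6) stop("expected 6 patch streams, got %d", (int)streams.size());
  std::vector<fmat> X(6);
  for (int s = 0; s < 6; ++s) {
    NumericMatrix m = streams[s];
    arma::mat d(m.begin(), m.nrow(), m.ncol(), false);
    X[s] = arma::conv_to<fmat>::from(d);
  }
  return X;
}

// forward a chunk of columns; each stream matrix is (P*P x n)
static fmat forward_chunk(const ParamMap& w, const NetCfg& cfg,
                          const std::vector<fmat>& X, const arma::uvec& idx) {
  const int N = idx.n_elem;
  fmat f8s[6];
  for (int s = 0; s < 6; ++s) {
    // gather samples into a 1 x (P*P*N) row with sample-major blocks
    fmat xb(1, (uword)X[s].n_rows * N);
    for (int n = 0; n < N; ++n)
      std::memcpy(xb.colptr((uword)n * X[s].n_rows), X[s].colptr(idx(n)),
                  X[s].n_rows * sizeof(float));
    f8s[s] = sub_forward(w, cfg, s, xb, N, nullptr);
  }
  return head_forward(w, f8s, nullptr);
}

// [[Rcpp::export]]
NumericVector nn_predict(List weights, List cfg_, List streams, int chunk = 64) {
  ParamMap w = weights_in(weights);
  NetCfg cfg = parse_cfg(cfg_);
  std::vector<fmat> X = streams_in(streams);
  const int n = X[0].n_cols;
  NumericVector out(n);
  for (int lo = 0; lo < n; lo += chunk) {
    const int hi = std::min(lo + chunk, n);
    arma::uvec idx = arma::regspace<arma::uvec>(lo, hi - 1);
    fmat p = forward_chunk(w, cfg, X, idx);
    for (int i = lo; i < hi; ++i) out[i] = p(0, i - lo);
  }
  return out;
}

// [[Rcpp::export]]
List nn_stage_shapes(List weights, List cfg_) {
  ParamMap w = weights_in(weights);
  NetCfg cfg = parse_cfg(cfg_);
  const int H0 = cfg.patch, H1 = (H0 + 1) / 2, H2 = (H1 + 1) / 2;
  fmat x(1, (uword)H0 * H0, arma::fill::zeros);
  SubCache C;
  fmat f8 = sub_forward(w, cfg, 0, x, 1, &C);
  List shp;
  shp["input"] = IntegerVector::create(H0, H0, 1);
  shp["c1"] = IntegerVector::create(H0, H0, (int)C.a1.n_rows);
  shp["p2"] = IntegerVector::create(H1, H1, (int)C.p2.n_rows);
  if (cfg.variant == MV_CNN)
    shp["block1"] = IntegerVector::create(H1, H1, (int)C.pb1.n_rows);
  else
    shp["block1"] = IntegerVector::create(H1, H1, (int)C.r1out.n_rows);
  if (cfg.variant == MV_SIR)
    shp["secondary"] = IntegerVector::create(H1, H1, (int)C.ep2.n_rows);
  shp["concat"] = IntegerVector::create(H1, H1, (int)C.cat.n_rows);
  shp["p3"] = IntegerVector::create(H2, H2, (int)C.p3.n_rows);
  shp["c4"] = IntegerVector::create(H2, H2, (int)C.c4.n_rows);
  if (cfg.variant == MV_CNN)
    shp["block2"] = IntegerVector::create(H2, H2, (int)C.pb2.n_rows);
  else
    shp["block2"] = IntegerVector::create(H2, H2, (int)C.r2out.n_rows);
  shp["p5"] = IntegerVector::create(H2, H2, (int)C.p5.n_rows);
  shp["flatten"] = IntegerVector::create((int)(C.p5.n_rows * H2 * H2));
  shp["f7"] = IntegerVector::create((int)C.f7.n_rows);
  shp["f8"] = IntegerVector::create((int)f8.n_rows);
  shp["fusion_input"] = IntegerVector::create((int)(6 * cfg.fc));
  shp["fusion"] = IntegerVector::create((int)P(w, "fu_w").n_cols);
  shp["output"] = IntegerVector::create(1);
  return shp;
}

// ---- exported: training ----------------------------------------------------

struct Adam {
  ParamMap m, v;
  double t = 0;
  void step(ParamMap& w, ParamMap& g, double lr, double wd, bool l2) {
    const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
    t += 1;
    for (ParamMap::iterator it = g.begin(); it != g.end(); ++it) {
      const std::string& k = it->first;
      fmat& gr = it->second;
      if (l2 && k.find("_b") == std::string::npos)   // decay weights, not biases
        gr += (float)wd * w[k];
      if (m.find(k) == m.end()) {
        m[k] = fmat(gr.n_rows, gr.n_cols, arma::fill::zeros);
        v[k] = fmat(gr.n_rows, gr.n_cols, arma::fill::zeros);
      }
      m[k] = (float)b1 * m[k] + (float)(1 - b1) * gr;
      v[k] = (float)b2 * v[k] + (float)(1 - b2) * arma::square(gr);
      const double mc = 1 - std::pow(b1, t), vc = 1 - std::pow(b2, t);
      w[k] -= (float)(lr / mc) * (m[k] / (arma::sqrt(v[k] / (float)vc) + (float)eps));
    }
  }
};

static double bce_mean(const fmat& p, const fvec& y, double eps) {
  double L = 0;
  for (uword i = 0; i < y.n_elem; ++i) {
    double pi = std::min(std::max((double)p(0, i), eps), 1 - eps);
    L += y(i) * std::log(pi) + (1 - y(i)) * std::log(1 - pi);
  }
  return -L / y.n_elem;
}

// [[Rcpp::export]]
List nn_train(List weights, List cfg_, List streams, NumericVector labels,
              IntegerVector train_idx, IntegerVector val_idx, List tcfg,
              int seed) {
  ParamMap w = weights_in(weights);
  NetCfg cfg = parse_cfg(cfg_);
  std::vector<fmat> X = streams_in(streams);
  const double lr0 = as<double>(tcfg["learning_rate"]);
  const double wd = as<double>(tcfg["weight_decay"]);
  const int batch = as<int>(tcfg["batch_size"]);
  const int epochs = as<int>(tcfg["epochs"]);
  const bool l2 = as<std::string>(tcfg["decay_mode"]) == "l2";
  const double eps = 1e-7;
  const int P0 = cfg.patch * cfg.patch;

  std::vector<int> tr(train_idx.begin(), train_idx.end());
  std::vector<int> va(val_idx.begin(), val_idx.end());
  std::mt19937 rng((unsigned)seed);
  Adam adam;

  NumericVector ep_loss(epochs), ep_acc(epochs), ep_vloss(epochs), ep_vacc(epochs);

  long step = 0;  // global iteration counter for per-step lr decay
  for (int e = 0; e < epochs; ++e) {
    std::shuffle(tr.begin(), tr.end(), rng);
    double loss_sum = 0; long correct = 0; long seen = 0;
    for (size_t lo = 0; lo < tr.size(); lo += batch) {
      const size_t hi = std::min(lo + (size_t)batch, tr.size());
      const int N = hi - lo;
      fvec y(N);
      fmat f8s[6];
      SubCache caches[6];
      for (int s = 0; s < 6; ++s) {
        fmat xb(1, (uword)P0 * N);
        for (int n = 0; n < N; ++n)
          std::memcpy(xb.colptr((uword)n * P0), X[s].colptr(tr[lo + n]),
                      P0 * sizeof(float));
        f8s[s] = sub_forward(w, cfg, s, xb, N, &caches[s]);
      }
      for (int n = 0; n < N; ++n) y(n) = (float)labels[tr[lo + n]];
      HeadCache hc;
      fmat p = head_forward(w, f8s, &hc);
      loss_sum += bce_mean(p, y, eps) * N;
      for (int n = 0; n < N; ++n) correct += ((p(0, n) >= 0.5f) == (y(n) >= 0.5f));
      seen += N;
      // gradient of mean BCE wrt logits
      fmat dZ = (p - arma::conv_to<fmat>::from(y.t())) / (float)N;
      ParamMap g;
      fmat dF8s[6];
      head_backward(w, g, hc, dZ, cfg.fc, dF8s);
      for (int s = 0; s < 6; ++s) sub_backward(w, g, cfg, s, caches[s], dF8s[s]);
      // "lr" decay mode follows the Keras convention: per-iteration decay
      const double lr = l2 ? lr0 : lr0 / (1.0 + wd * step);
      adam.step(w, g, lr, wd, l2);
      ++step;
      Rcpp::checkUserInterrupt();
    }
    ep_loss[e] = loss_sum / std::max<long>(seen, 1);
    ep_acc[e] = (double)correct / std::max<long>(seen, 1);
    // validation pass
    double vloss = 0; long vcorrect = 0;
    if (!va.empty()) {
      for (size_t lo = 0; lo < va.size(); lo += batch) {
        const size_t hi = std::min(lo + (size_t)batch, va.size());
        const int N = hi - lo;
        arma::uvec idx(N);
        for (int n = 0; n < N; ++n) idx(n) = va[lo + n];
        fmat p = forward_chunk(w, cfg, X, idx);
        fvec y(N);
        for (int n = 0; n < N; ++n) y(n) = (float)labels[va[lo + n]];
        vloss += bce_mean(p, y, eps) * N;
        for (int n = 0; n < N; ++n) vcorrect += ((p(0, n) >= 0.5f) == (y(n) >= 0.5f));
      }
      vloss /= va.size();
    }
    ep_vloss[e] = va.empty() ? NA_REAL : vloss;
    ep_vacc[e] = va.empty() ? NA_REAL : (double)vcorrect / va.size();
  }

  DataFrame curve = DataFrame::create(
      _["epoch"] = seq_len(epochs), _["loss"] = ep_loss, _["acc"] = ep_acc,
      _["val_loss"] = ep_vloss, _["val_acc"] = ep_vacc);
  return List::create(_["weights"] = weights_out(w), _["curve"] = curve);
}

// ---- exported: single residual block (for direct unit testing) -------------

// [[Rcpp::export]]
NumericMatrix nn_residual_block(NumericMatrix x, int H, int W,
                                NumericMatrix w1, NumericVector b1,
                                NumericMatrix w2, NumericVector b2,
                                NumericMatrix w3, NumericVector b3) {
  arma::mat xd(x.begin(), x.nrow(), x.ncol(), false);
  fmat A = arma::conv_to<fmat>::from(xd);   // C x (H*W), single sample
  if ((int)A.n_cols != H * W) stop("residual block: x must be C x (H*W)");
  fmat W1 = arma::conv_to<fmat>::from(arma::mat(w1.begin(), w1.nrow(), w1.ncol(), false));
  fmat W2 = arma::conv_to<fmat>::from(arma::mat(w2.begin(), w2.nrow(), w2.ncol(), false));
  fmat W3 = arma::conv_to<fmat>::from(arma::mat(w3.begin(), w3.nrow(), w3.ncol(), false));
  if ((int)W3.n_cols != (int)A.n_rows)
    stop("residual block: output width %d != input channels %d (identity skip not addable)",
         (int)W3.n_cols, (int)A.n_rows);
  if ((int)W1.n_rows != (int)A.n_rows)
    stop("residual block: first 1x1 conv expects %d input channels, got %d",
         (int)W1.n_rows, (int)A.n_rows);
  fmat B1(b1.size(), 1), B2(b2.size(), 1), B3(b3.size(), 1);
  for (int i = 0; i < b1.size(); ++i) B1(i, 0) = (float)b1[i];
  for (int i = 0; i < b2.size(); ++i) B2(i, 0) = (float)b2[i];
  for (int i = 0; i < b3.size(); ++i) B3(i, 0) = (float)b3[i];
  fmat a = conv1_fwd(A, W1, B1, true);
  fmat b = conv3_fwd(a, W2, B2, H, W, 1, true);
  fmat c = conv1_fwd(b, W3, B3, false);
  c += A;
  relu_(c);
  arma::mat out = arma::conv_to<arma::mat>::from(c);
  return wrap(out);
}
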