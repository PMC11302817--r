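// Dual-channel CNN for delivery-error classification, trained with ADAM on
// softmax cross-entropy.  Architecture (same-padded 3x3 convolutions,
// floor-divided 2x2 max pools):
//
//   (2,H,W) -stem-> (16,H,W) -conv/BN/ReLU/pool-> (16,H/2,W/2)
//           -conv/BN/ReLU/pool-> (32,H/4,W/4) -conv/BN/ReLU-> (64,H/4,W/4)
//           -GAP-> 64 -FC-> 128 -dropout-> FC -> 5 -softmax->
//
// Everything is implemented here (im2col convolutions as GEMMs, batch
// normalization with running statistics, inverted dropout, ADAM) in single
// precision for CPU throughput.  Activations are stored as (B*H*W) x C
// matrices with row-major pixel order within each sample block, so a
// convolution tap is a constant shift of a column plus edge zeroing.
//
// Determinism: all randomness (epoch shuffles, dropout masks) comes from
// one std::mt19937 seeded by the caller.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

#include <random>

using namespace arma;

static const float BN_EPS = 1e-5f;
static const float BN_MOM = 0.1f;

// --- im2col via shifted columns -----------------------------------------

struct ConvCtx {
  int H, W, HW;
  int shift[9];                       // pixel-index shift per tap
  std::vector<std::vector<int>> edge; // per tap: pixels whose lateral
                                      // neighbour wraps rows (must be 0)
};

static ConvCtx make_ctx(int H, int W) {
  ConvCtx c;
  c.H = H; c.W = W; c.HW = H * W;
  c.edge.resize(9);
  for (int dy = -1; dy <= 1; ++dy)
    for (int dx = -1; dx <= 1; ++dx) {
      int q = (dy + 1) * 3 + (dx + 1);
      c.shift[q] = dy * W + dx;
      if (dx != 0)
        for (int r = 0; r < H; ++r) {
          int col = (dx == 1) ? W - 1 : 0;   // neighbour falls off the row
          c.edge[q].push_back(r * W + col);
        }
    }
  return c;
}

// writes into X (resized only when dimensions change, so the buffer is
// reused across training steps)
static void im2col(const fmat& A, int B, const ConvCtx& c, fmat& X) {
  const int Cin = A.n_cols, HW = c.HW;
  X.set_size(A.n_rows, (uword)Cin * 9);
  for (int k = 0; k < Cin; ++k) {
    const float* src = A.colptr(k);
    for (int q = 0; q < 9; ++q) {
      float* dst = X.colptr((uword)k * 9 + q);
      const int s = c.shift[q];
      const int p0 = std::max(0, -s), p1 = std::min(HW, HW - s);
      for (int b = 0; b < B; ++b) {
        float* d = dst + (size_t)b * HW;
        const float* so = src + (size_t)b * HW + s;
        for (int p = 0; p < p0; ++p) d[p] = 0.0f;
        std::memcpy(d + p0, so + p0, (size_t)(p1 - p0) * sizeof(float));
        for (int p = p1; p < HW; ++p) d[p] = 0.0f;
        for (int p : c.edge[q]) d[p] = 0.0f;
      }
    }
  }
}

// accumulate dX (im2col layout) back into dA
static void col2im(const fmat& dX, int B, const ConvCtx& c, fmat& dA) {
  const int Cin = dA.n_cols, HW = c.HW;
  dA.zeros();
  for (int k = 0; k < Cin; ++k) {
    float* dst = dA.colptr(k);
    for (int q = 0; q < 9; ++q) {
      const float* src = dX.colptr((uword)k * 9 + q);
      const int s = c.shift[q];
      const int p0 = std::max(0, -s), p1 = std::min(HW, HW - s);
      for (int b = 0; b < B; ++b) {
        float* d = dst + (size_t)b * HW + s;
        const float* so = src + (size_t)b * HW;
        std::vector<char> skip;            // lateral-edge taps do not flow back
        if (!c.edge[q].empty()) {
          skip.assign(HW, 0);
          for (int p : c.edge[q]) skip[p] = 1;
          for (int p = p0; p < p1; ++p) if (!skip[p]) d[p] += so[p];
        } else {
          for (int p = p0; p < p1; ++p) d[p] += so[p];
        }
      }
    }
  }
}

// --- layers --------------------------------------------------------------

struct BNCache { frowvec invstd; fmat xhat; };

static fmat bn_forward(const fmat& Z, const frowvec& g, const frowvec& be,
                       frowvec& rm, frowvec& rv, bool train, BNCache& cache) {
  if (train) {
    const float N = (float)Z.n_rows;
    frowvec mu = mean(Z, 0);
    fmat cz = Z; cz.each_row() -= mu;
    frowvec var = sum(square(cz), 0) / N;
    cache.invstd = 1.0f / sqrt(var + BN_EPS);
    cz.each_row() %= cache.invstd;
    cache.xhat = cz;
    rm = (1.0f - BN_MOM) * rm + BN_MOM * mu;
    rv = (1.0f - BN_MOM) * rv + BN_MOM * var;
    fmat y = cz; y.each_row() %= g; y.each_row() += be;
    return y;
  }
  frowvec invstd = 1.0f / sqrt(rv + BN_EPS);
  fmat y = Z; y.each_row() -= rm; y.each_row() %= (invstd % g);
  y.each_row() += be;
  return y;
}

static fmat bn_backward(const fmat& dY, const frowvec& g, const BNCache& cache,
                        frowvec& gG, frowvec& gBe) {
  const float N = (float)dY.n_rows;
  gBe = sum(dY, 0);
  gG = sum(dY % cache.xhat, 0);
  fmat dX = N * dY;
  dX.each_row() -= gBe;
  fmat t = cache.xhat; t.each_row() %= gG;
  dX -= t;
  dX.each_row() %= (g % cache.invstd / N);
  return dX;
}

static fmat pool_forward(const fmat& A, int B, int H, int W,
                         umat& argmax, int& H2, int& W2) {
  H2 = H / 2; W2 = W / 2;
  const int HW = H * W, HW2 = H2 * W2, C = A.n_cols;
  fmat P((uword)B * HW2, C, fill::none);
  argmax.set_size((uword)B * HW2, C);
  for (int k = 0; k < C; ++k) {
    const float* a = A.colptr(k);
    float* p = P.colptr(k);
    uword* am = argmax.colptr(k);
    for (int b = 0; b < B; ++b)
      for (int r2 = 0; r2 < H2; ++r2)
        for (int c2 = 0; c2 < W2; ++c2) {
          const int base = b * HW + 2 * r2 * W + 2 * c2;
          int best = base;
          if (a[base + 1] > a[best]) best = base + 1;
          if (a[base + W] > a[best]) best = base + W;
          if (a[base + W + 1] > a[best]) best = base + W + 1;
          const int o = b * HW2 + r2 * W2 + c2;
          p[o] = a[best];
          am[o] = best;
        }
  }
  return P;
}

static void pool_backward(const fmat& dP, const umat& argmax,
                          uword rows_in, fmat& dA) {
  dA.zeros(rows_in, dP.n_cols);
  for (uword k = 0; k < dP.n_cols; ++k) {
    float* d = dA.colptr(k);
    const float* s = dP.colptr(k);
    const uword* am = argmax.colptr(k);
    for (uword i = 0; i < dP.n_rows; ++i) d[am[i]] += s[i];
  }
}

static fmat gap_forward(const fmat& A, int B, int HW) {
  fmat G(B, A.n_cols, fill::none);
  for (int b = 0; b < B; ++b)
    G.row(b) = mean(A.rows((uword)b * HW, (uword)(b + 1) * HW - 1), 0);
  return G;
}

static fmat gap_backward(const fmat& dG, int B, int HW) {
  fmat dA((uword)B * HW, dG.n_cols, fill::none);
  for (int b = 0; b < B; ++b)
    dA.rows((uword)b * HW, (uword)(b + 1) * HW - 1) =
      repmat(dG.row(b) / (float)HW, HW, 1);
  return dA;
}

// --- parameters ----------------------------------------------------------

struct Params {
  fmat Ws, W1, W2, W3, Wf1, Wf2;
  frowvec bs, b1, b2, b3, bf1, bf2;
  frowvec g1, be1, rm1, rv1;
  frowvec g2, be2, rm2, rv2;
  frowvec g3, be3, rm3, rv3;
};

static frowvec as_frow(SEXP x) {
  Rcpp::NumericVector v(x);
  frowvec out(v.size());
  for (int i = 0; i < v.size(); ++i) out(i) = (float)v[i];
  return out;
}

static fmat as_fmat(SEXP x) {
  Rcpp::NumericMatrix m(x);
  fmat out(m.nrow(), m.ncol());
  for (int j = 0; j < m.ncol(); ++j)
    for (int i = 0; i < m.nrow(); ++i) out(i, j) = (float)m(i, j);
  return out;
}

static Params params_from_list(const Rcpp::List& L) {
  Params p;
  p.Ws = as_fmat(L["Ws"]);   p.bs = as_frow(L["bs"]);
  p.W1 = as_fmat(L["W1"]);   p.b1 = as_frow(L["b1"]);
  p.W2 = as_fmat(L["W2"]);   p.b2 = as_frow(L["b2"]);
  p.W3 = as_fmat(L["W3"]);   p.b3 = as_frow(L["b3"]);
  p.Wf1 = as_fmat(L["Wf1"]); p.bf1 = as_frow(L["bf1"]);
  p.Wf2 = as_fmat(L["Wf2"]); p.bf2 = as_frow(L["bf2"]);
  p.g1 = as_frow(L["g1"]); p.be1 = as_frow(L["be1"]);
  p.rm1 = as_frow(L["rm1"]); p.rv1 = as_frow(L["rv1"]);
  p.g2 = as_frow(L["g2"]); p.be2 = as_frow(L["be2"]);
  p.rm2 = as_frow(L["rm2"]); p.rv2 = as_frow(L["rv2"]);
  p.g3 = as_frow(L["g3"]); p.be3 = as_frow(L["be3"]);
  p.rm3 = as_frow(L["rm3"]); p.rv3 = as_frow(L["rv3"]);
  return p;
}

static SEXP num(const fmat& m) {
  Rcpp::NumericMatrix out(m.n_rows, m.n_cols);
  for (uword j = 0; j < m.n_cols; ++j)
    for (uword i = 0; i < m.n_rows; ++i) out(i, j) = m(i, j);
  return out;
}

static SEXP num(const frowvec& v) {
  Rcpp::NumericVector out(v.n_elem);
  for (uword i = 0; i < v.n_elem; ++i) out[i] = v(i);
  return out;
}

static Rcpp::List params_to_list(const Params& p) {
  return Rcpp::List::create(
    Rcpp::Named("Ws") = num(p.Ws), Rcpp::Named("bs") = num(p.bs),
    Rcpp::Named("W1") = num(p.W1), Rcpp::Named("b1") = num(p.b1),
    Rcpp::Named("g1") = num(p.g1), Rcpp::Named("be1") = num(p.be1),
    Rcpp::Named("rm1") = num(p.rm1), Rcpp::Named("rv1") = num(p.rv1),
    Rcpp::Named("W2") = num(p.W2), Rcpp::Named("b2") = num(p.b2),
    Rcpp::Named("g2") = num(p.g2), Rcpp::Named("be2") = num(p.be2),
    Rcpp::Named("rm2") = num(p.rm2), Rcpp::Named("rv2") = num(p.rv2),
    Rcpp::Named("W3") = num(p.W3), Rcpp::Named("b3") = num(p.b3),
    Rcpp::Named("g3") = num(p.g3), Rcpp::Named("be3") = num(p.be3),
    Rcpp::Named("rm3") = num(p.rm3), Rcpp::Named("rv3") = num(p.rv3),
    Rcpp::Named("Wf1") = num(p.Wf1), Rcpp::Named("bf1") = num(p.bf1),
    Rcpp::Named("Wf2") = num(p.Wf2), Rcpp::Named("bf2") = num(p.bf2));
}

// --- forward / backward --------------------------------------------------

struct Cache {
  int B, H, W, H2, W2, H3, W3;
  fmat A0, Xcol0, Z0, Xcol1, R1, P1, Xcol2, R2, P2, Xcol3, R3;
  fmat M1, M2, M3;                 // ReLU masks
  umat arg1, arg2;
  BNCache bn1, bn2, bn3;
  fmat G, F1, Dmask, probs;
  fmat dXcol1, dXcol2, dXcol3, dP1, dP2, dR1, dR2, dZ0; // backward scratch
  float loss;
};

// X rows: one sample = [channel0 pixels row-major, channel1 pixels ...]
static void gather_batch(const fmat& X, const uvec& idx, int HW, fmat& A0) {
  const int B = idx.n_elem;
  A0.set_size((uword)B * HW, 2);
  for (int b = 0; b < B; ++b)
    for (int k = 0; k < 2; ++k)
      for (int p = 0; p < HW; ++p)
        A0((uword)b * HW + p, k) = X(idx(b), (uword)k * HW + p);
}

static void forward(const Params& p, const fmat& A0, int B,
                    const ConvCtx& c0, const ConvCtx& c1, const ConvCtx& c2,
                    bool train, float dropout, std::mt19937* rng,
                    Cache& K) {
  K.B = B;
  // stem (no activation, per the architecture table)
  K.A0 = A0;
  im2col(A0, B, c0, K.Xcol0);
  K.Z0 = K.Xcol0 * p.Ws; K.Z0.each_row() += p.bs;
  // block 1
  im2col(K.Z0, B, c0, K.Xcol1);
  fmat Z1 = K.Xcol1 * p.W1; Z1.each_row() += p.b1;
  fmat Y1 = bn_forward(Z1, p.g1, p.be1,
                       const_cast<Params&>(p).rm1, const_cast<Params&>(p).rv1,
                       train, K.bn1);
  K.M1 = conv_to<fmat>::from(Y1 > 0.0f);
  K.R1 = Y1 % K.M1;
  K.P1 = pool_forward(K.R1, B, c0.H, c0.W, K.arg1, K.H2, K.W2);
  // block 2
  im2col(K.P1, B, c1, K.Xcol2);
  fmat Z2 = K.Xcol2 * p.W2; Z2.each_row() += p.b2;
  fmat Y2 = bn_forward(Z2, p.g2, p.be2,
                       const_cast<Params&>(p).rm2, const_cast<Params&>(p).rv2,
                       train, K.bn2);
  K.M2 = conv_to<fmat>::from(Y2 > 0.0f);
  K.R2 = Y2 % K.M2;
  K.P2 = pool_forward(K.R2, B, c1.H, c1.W, K.arg2, K.H3, K.W3);
  // block 3
  im2col(K.P2, B, c2, K.Xcol3);
  fmat Z3 = K.Xcol3 * p.W3; Z3.each_row() += p.b3;
  fmat Y3 = bn_forward(Z3, p.g3, p.be3,
                       const_cast<Params&>(p).rm3, const_cast<Params&>(p).rv3,
                       train, K.bn3);
  K.M3 = conv_to<fmat>::from(Y3 > 0.0f);
  K.R3 = Y3 % K.M3;
  // head
  K.G = gap_forward(K.R3, B, c2.HW);
  K.F1 = K.G * p.Wf1; K.F1.each_row() += p.bf1;
  if (train && dropout > 0.0f && rng) {
    std::bernoulli_distribution keep(1.0 - dropout);
    K.Dmask.set_size(K.F1.n_rows, K.F1.n_cols);
    const float scale = 1.0f / (1.0f - dropout);
    for (uword j = 0; j < K.F1.n_cols; ++j)
      for (uword i = 0; i < K.F1.n_rows; ++i)
        K.Dmask(i, j) = keep(*rng) ? scale : 0.0f;
    K.F1 %= K.Dmask;
  } else {
    K.Dmask.reset();
  }
  fmat logits = K.F1 * p.Wf2; logits.each_row() += p.bf2;
  logits.each_col() -= max(logits, 1);
  fmat e = exp(logits);
  K.probs = e.each_col() / sum(e, 1);
}

static float ce_loss(const fmat& probs, const uvec& y) {
  float L = 0;
  for (uword b = 0; b < y.n_elem; ++b)
    L -= std::log(std::max(probs(b, y(b)), 1e-12f));
  return L / y.n_elem;
}

static void backward(const Params& p, Cache& K, const uvec& y,
                     const ConvCtx& c0, const ConvCtx& c1, const ConvCtx& c2,
                     Params& g) {
  const int B = K.B;
  fmat dlog = K.probs;
  for (int b = 0; b < B; ++b) dlog(b, y(b)) -= 1.0f;
  dlog /= (float)B;
  g.Wf2 = K.F1.t() * dlog; g.bf2 = sum(dlog, 0);
  fmat dF1 = dlog * p.Wf2.t();
  if (!K.Dmask.is_empty()) dF1 %= K.Dmask;
  g.Wf1 = K.G.t() * dF1; g.bf1 = sum(dF1, 0);
  fmat dG = dF1 * p.Wf1.t();
  fmat dR3 = gap_backward(dG, B, c2.HW);
  dR3 %= K.M3;
  fmat dZ3 = bn_backward(dR3, p.g3, K.bn3, g.g3, g.be3);
  g.W3 = K.Xcol3.t() * dZ3; g.b3 = sum(dZ3, 0);
  K.dXcol3 = dZ3 * p.W3.t();
  K.dP2.set_size(K.P2.n_rows, K.P2.n_cols);
  col2im(K.dXcol3, B, c2, K.dP2);
  pool_backward(K.dP2, K.arg2, K.R2.n_rows, K.dR2);
  K.dR2 %= K.M2;
  fmat dZ2 = bn_backward(K.dR2, p.g2, K.bn2, g.g2, g.be2);
  g.W2 = K.Xcol2.t() * dZ2; g.b2 = sum(dZ2, 0);
  K.dXcol2 = dZ2 * p.W2.t();
  K.dP1.set_size(K.P1.n_rows, K.P1.n_cols);
  col2im(K.dXcol2, B, c1, K.dP1);
  pool_backward(K.dP1, K.arg1, K.R1.n_rows, K.dR1);
  K.dR1 %= K.M1;
  fmat dZ1 = bn_backward(K.dR1, p.g1, K.bn1, g.g1, g.be1);
  g.W1 = K.Xcol1.t() * dZ1; g.b1 = sum(dZ1, 0);
  K.dXcol1 = dZ1 * p.W1.t();
  K.dZ0.set_size(K.Z0.n_rows, K.Z0.n_cols);
  col2im(K.dXcol1, B, c0, K.dZ0);
  g.Ws = K.Xcol0.t() * K.dZ0; g.bs = sum(K.dZ0, 0);
}

// --- ADAM ----------------------------------------------------------------

template <typename T>
static void adam_step(T& w, T& m, T& v, const T& grad,
                      float lr, float b1, float b2, float eps, int t) {
  m = b1 * m + (1.0f - b1) * grad;
  v = b2 * v + (1.0f - b2) * (grad % grad);
  const float c1 = 1.0f - std::pow(b1, (float)t);
  const float c2 = 1.0f - std::pow(b2, (float)t);
  w -= lr * (m / c1) / (sqrt(v / c2) + eps);
}

struct Adam {
  Params m, v;
  int t = 0;
  explicit Adam(const Params& p) {
    auto zl = [](const fmat& x) { return fmat(x.n_rows, x.n_cols, fill::zeros); };
    auto zr = [](const frowvec& x) { return frowvec(x.n_elem, fill::zeros); };
    m.Ws = zl(p.Ws); m.W1 = zl(p.W1); m.W2 = zl(p.W2); m.W3 = zl(p.W3);
    m.Wf1 = zl(p.Wf1); m.Wf2 = zl(p.Wf2);
    m.bs = zr(p.bs); m.b1 = zr(p.b1); m.b2 = zr(p.b2); m.b3 = zr(p.b3);
    m.bf1 = zr(p.bf1); m.bf2 = zr(p.bf2);
    m.g1 = zr(p.g1); m.be1 = zr(p.be1); m.g2 = zr(p.g2); m.be2 = zr(p.be2);
    m.g3 = zr(p.g3); m.be3 = zr(p.be3);
    v = m;
  }
  void update(Params& p, const Params& g, float lr) {
    ++t;
    const float b1 = 0.9f, b2 = 0.999f, eps = 1e-8f;
    adam_step(p.Ws, m.Ws, v.Ws, g.Ws, lr, b1, b2, eps, t);
    adam_step(p.bs, m.bs, v.bs, g.bs, lr, b1, b2, eps, t);
    adam_step(p.W1, m.W1, v.W1, g.W1, lr, b1, b2, eps, t);
    adam_step(p.b1, m.b1, v.b1, g.b1, lr, b1, b2, eps, t);
    adam_step(p.g1, m.g1, v.g1, g.g1, lr, b1, b2, eps, t);
    adam_step(p.be1, m.be1, v.be1, g.be1, lr, b1, b2, eps, t);
    adam_step(p.W2, m.W2, v.W2, g.W2, lr, b1, b2, eps, t);
    adam_step(p.b2, m.b2, v.b2, g.b2, lr, b1, b2, eps, t);
    adam_step(p.g2, m.g2, v.g2, g.g2, lr, b1, b2, eps, t);
    adam_step(p.be2, m.be2, v.be2, g.be2, lr, b1, b2, eps, t);
    adam_step(p.W3, m.W3, v.W3, g.W3, lr, b1, b2, eps, t);
    adam_step(p.b3, m.b3, v.b3, g.b3, lr, b1, b2, eps, t);
    adam_step(p.g3, m.g3, v.g3, g.g3, lr, b1, b2, eps, t);
    adam_step(p.be3, m.be3, v.be3, g.be3, lr, b1, b2, eps, t);
    adam_step(p.Wf1, m.Wf1, v.Wf1, g.Wf1, lr, b1, b2, eps, t);
    adam_step(p.bf1, m.bf1, v.bf1, g.bf1, lr, b1, b2, eps, t);
    adam_step(p.Wf2, m.Wf2, v.Wf2, g.Wf2, lr, b1, b2, eps, t);
    adam_step(p.bf2, m.bf2, v.bf2, g.bf2, lr, b1, b2, eps, t);
  }
};

// --- exported entry points ----------------------------------------------

// [[Rcpp::export(name = ".cnn_train")]]
Rcpp::List cnn_train(Rcpp::List params, const arma::mat& X,
                     const arma::ivec& y, int H, int W,
                     int epochs, int batch, double lr,
                     double dropout, int seed) {
  if (X.n_rows == 0) Rcpp::stop("empty training set");
  Params p = params_from_list(params);
  ConvCtx c0 = make_ctx(H, W);
  ConvCtx c1 = make_ctx(H / 2, W / 2);
  ConvCtx c2 = make_ctx(H / 4, W / 4);
  fmat Xf = conv_to<fmat>::from(X);
  uvec yy = conv_to<uvec>::from(y);
  std::mt19937 rng((unsigned)seed);
  const int N = X.n_rows;
  std::vector<int> order(N);
  for (int i = 0; i < N; ++i) order[i] = i;
  Adam opt(p);
  Cache K;
  Params g;
  fmat A0;
  std::vector<double> loss_hist;
  loss_hist.reserve(epochs);
  for (int e = 0; e < epochs; ++e) {
    std::shuffle(order.begin(), order.end(), rng);
    double esum = 0; int nb = 0;
    for (int start = 0; start < N; start += batch) {
      const int bsz = std::min(batch, N - start);
      uvec idx(bsz);
      for (int i = 0; i < bsz; ++i) idx(i) = order[start + i];
      gather_batch(Xf, idx, c0.HW, A0);
      forward(p, A0, bsz, c0, c1, c2, true, (float)dropout, &rng, K);
      const float L = ce_loss(K.probs, yy.elem(idx));
      if (!std::isfinite(L))
        Rcpp::stop("non-finite training loss at epoch %d", e + 1);
      backward(p, K, yy.elem(idx), c0, c1, c2, g);
      opt.update(p, g, (float)lr);
      esum += L; ++nb;
    }
    loss_hist.push_back(esum / nb);
    Rcpp::checkUserInterrupt();
  }
  return Rcpp::List::create(Rcpp::Named("params") = params_to_list(p),
                            Rcpp::Named("loss") = loss_hist);
}

// [[Rcpp::export(name = ".cnn_predict")]]
arma::mat cnn_predict(Rcpp::List params, const arma::mat& X, int H, int W,
                      bool batch_stats = false) {
  Params p = params_from_list(params);
  ConvCtx c0 = make_ctx(H, W);
  ConvCtx c1 = make_ctx(H / 2, W / 2);
  ConvCtx c2 = make_ctx(H / 4, W / 4);
  fmat Xf = conv_to<fmat>::from(X);
  const int N = X.n_rows;
  mat out(N, 5);
  Cache K;
  fmat A0;
  const int chunk = 64;
  for (int start = 0; start < N; start += chunk) {
    const int bsz = std::min(chunk, N - start);
    uvec idx(bsz);
    for (int i = 0; i < bsz; ++i) idx(i) = start + i;
    gather_batch(Xf, idx, c0.HW, A0);
    forward(p, A0, bsz, c0, c1, c2, batch_stats, 0.0f, nullptr, K);
    for (int i = 0; i < bsz; ++i)
      for (int j = 0; j < 5; ++j) out(start + i, j) = K.probs(i, j);
  }
  return out;
}

// batch-mode loss and gradients, dropout off (for gradient checking)
// [[Rcpp::export(name = ".cnn_grad")]]
Rcpp::List cnn_grad(Rcpp::List params, const arma::mat& X,
                    const arma::ivec& y, int H, int W) {
  Params p = params_from_list(params);
  ConvCtx c0 = make_ctx(H, W);
  ConvCtx c1 = make_ctx(H / 2, W / 2);
  ConvCtx c2 = make_ctx(H / 4, W / 4);
  fmat Xf = conv_to<fmat>::from(X);
  uvec yy = conv_to<uvec>::from(y);
  uvec idx = regspace<uvec>(0, X.n_rows - 1);
  fmat A0;
  gather_batch(Xf, idx, c0.HW, A0);
  Cache K;
  forward(p, A0, X.n_rows, c0, c1, c2, true, 0.0f, nullptr, K);
  Params g;
  backward(p, K, yy, c0, c1, c2, g);
  g.rm1 = p.rm1; g.rv1 = p.rv1; g.rm2 = p.rm2; g.rv2 = p.rv2;
  g.rm3 = p.rm3; g.rv3 = p.rv3;
  return Rcpp::List::create(Rcpp::Named("loss") = ce_loss(K.probs, yy),
                            Rcpp::Named("grads") = params_to_list(g));
}

// activation shape trace of a forward pass on one instance
// [[Rcpp::export(name = ".cnn_trace")]]
Rcpp::List cnn_trace(Rcpp::List params, const arma::mat& X, int H, int W) {
  Params p = params_from_list(params);
  ConvCtx c0 = make_ctx(H, W);
  ConvCtx c1 = make_ctx(H / 2, W / 2);
  ConvCtx c2 = make_ctx(H / 4, W / 4);
  fmat Xf = conv_to<fmat>::from(X);
  uvec idx(1); idx(0) = 0;
  fmat A0;
  gather_batch(Xf, idx, c0.HW, A0);
  Cache K;
  forward(p, A0, 1, c0, c1, c2, false, 0.0f, nullptr, K);
  auto dim3 = [](const fmat& a, int HH, int WW) {
    return Rcpp::IntegerVector::create((int)a.n_cols, HH, WW);
  };
  return Rcpp::List::create(
    Rcpp::Named("stem") = dim3(K.Z0, c0.H, c0.W),
    Rcpp::Named("conv1") = dim3(K.R1, c0.H, c0.W),
    Rcpp::Named("pool1") = dim3(K.P1, c1.H, c1.W),
    Rcpp::Named("conv2") = dim3(K.R2, c1.H, c1.W),
    Rcpp::Named("pool2") = dim3(K.P2, c2.H, c2.W),
    Rcpp::Named("conv3") = dim3(K.R3, c2.H, c2.W),
    Rcpp::Named("gap") = Rcpp::IntegerVector::create((int)K.G.n_cols),
    Rcpp::Named("fc1") = Rcpp::IntegerVector::create((int)K.F1.n_cols),
    Rcpp::Named("out") = Rcpp::IntegerVector::create((int)K.probs.n_cols));
}
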