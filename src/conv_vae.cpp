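// Convolutional VAE kernels.
//
// Encoder: stride-2 3x3 conv layers (computed as stride-1 conv + 2x
// subsample), ReLU. Decoder: nearest-neighbour 2x resize + 3x3 conv, leaky
// ReLU; final 3x3 conv to one channel + sigmoid. A combined
// forward/backward step keeps all buffers on the C++ side.
//
// Feature maps are stored channels-first with a one-pixel zero border baked
// in: arma::mat of shape (C, Sp*N) with Sp = (H+2)*(W+2) and column index
// s + Sp*n, s = h + (H+2)*w (h fastest, h/w in 0..H+1 including the pad).
// A 3x3 convolution is then nine aliased GEMMs, one per kernel offset, on
// column-shifted views of the same memory; shifted reads that cross sample
// or pad boundaries only ever land in pad columns, which are discarded when
// the interior is re-extracted. Kernels are (9*Cin, Cout) matrices with row
// index kh + 3*(kw + 3*c), matching the R-side parameter lists.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::vec;

struct Geom {
  int H, W, N;
  int ph() const { return H + 2; }
  int sp() const { return (H + 2) * (W + 2); }
  size_t cols() const { return (size_t)sp() * N; }
};

// zero-copy alias of a column range [c0, c0+len) of M
static mat alias_cols(const mat &M, size_t c0, size_t len) {
  return mat(const_cast<double *>(M.colptr(c0)), M.n_rows, len, false, true);
}

// offset (in columns) of kernel tap (kh, kw) relative to the output pixel
static inline long tap_off(const Geom &g, int kh, int kw) {
  return (kh - 1) + (long)g.ph() * (kw - 1);
}

// kernel slice (Cin x Cout) for tap (kh, kw)
static mat tap_w(const mat &W9, int kh, int kw, int Cin) {
  mat out(Cin, W9.n_cols);
  for (int c = 0; c < Cin; ++c)
    out.row(c) = W9.row(kh + 3 * (kw + 3 * c));
  return out;
}

// Y (Cout, cols) += sum_taps tap_w' * shift(X); Y must start zeroed
static void conv9(const mat &X, const mat &W9, mat &Y, const Geom &g) {
  const int Cin = X.n_rows;
  const size_t nc = g.cols();
  for (int kw = 0; kw < 3; ++kw)
    for (int kh = 0; kh < 3; ++kh) {
      const long o = tap_off(g, kh, kw);
      const size_t lo = o < 0 ? (size_t)(-o) : 0;
      const size_t hi = o > 0 ? nc - o : nc;  // exclusive
      if (hi <= lo) continue;
      mat Wk = tap_w(W9, kh, kw, Cin);
      mat Ysub = alias_cols(Y, lo, hi - lo);
      Ysub += Wk.t() * alias_cols(X, lo + o, hi - lo);
    }
}

// backward: dX += sum_taps shift'(tap_w * dY); dW9 += gathered products
static void conv9_back(const mat &X, const mat &W9, const mat &dY, mat &dX,
                       mat &dW9, const Geom &g) {
  const int Cin = X.n_rows;
  const size_t nc = g.cols();
  for (int kw = 0; kw < 3; ++kw)
    for (int kh = 0; kh < 3; ++kh) {
      const long o = tap_off(g, kh, kw);
      const size_t lo = o < 0 ? (size_t)(-o) : 0;
      const size_t hi = o > 0 ? nc - o : nc;
      if (hi <= lo) continue;
      mat dYsub = alias_cols(dY, lo, hi - lo);
      mat Xsub = alias_cols(X, lo + o, hi - lo);
      mat dWk = Xsub * dYsub.t();  // (Cin, Cout)
      for (int c = 0; c < Cin; ++c)
        dW9.row(kh + 3 * (kw + 3 * c)) += dWk.row(c);
      mat Wk = tap_w(W9, kh, kw, Cin);
      mat dXsub = alias_cols(dX, lo + o, hi - lo);
      dXsub += Wk * dYsub;
    }
}

// iterate the interior columns ((n, w) blocks of H consecutive columns)
template <typename F>
static void interior(const Geom &g, F f) {
  for (int n = 0; n < g.N; ++n)
    for (int w = 1; w <= g.W; ++w)
      f((size_t)g.sp() * n + (size_t)g.ph() * w + 1, (size_t)g.H);
}

// zero pad columns, add bias + activation on the interior
static void finish_layer(mat &Y, const vec &b, const Geom &g, double slope) {
  mat Yc = Y;
  Y.zeros();
  interior(g, [&](size_t c0, size_t len) {
    for (size_t j = 0; j < len; ++j) {
      double *dst = Y.colptr(c0 + j);
      const double *src = Yc.colptr(c0 + j);
      for (arma::uword r = 0; r < Y.n_rows; ++r) {
        double v = src[r] + b[r];
        dst[r] = v > 0 ? v : slope * v;  // slope 0 => ReLU
      }
    }
  });
}

// derivative mask from post-activations (monotone sign-preserving acts)
static mat act_back(const mat &dY, const mat &act, double slope) {
  mat out(arma::size(dY), arma::fill::zeros);
  for (size_t i = 0; i < dY.n_elem; ++i)
    if (act[i] != 0.0) out[i] = act[i] > 0 ? dY[i] : slope * dY[i];
  return out;
}

// padded map (C, Sp*N) at (H, W) -> padded map at (H/2, W/2), taking the
// top-left pixel of each 2x2 block (equivalent to stride-2 convolution)
static mat subsample2(const mat &X, const Geom &g, Geom &g2) {
  g2 = Geom{g.H / 2, g.W / 2, g.N};
  mat out(X.n_rows, g2.cols(), arma::fill::zeros);
  for (int n = 0; n < g.N; ++n)
    for (int w2 = 1; w2 <= g2.W; ++w2) {
      const int w = 2 * w2 - 1;
      for (int h2 = 1; h2 <= g2.H; ++h2) {
        const int h = 2 * h2 - 1;
        out.col((size_t)g2.sp() * n + (size_t)g2.ph() * w2 + h2) =
            X.col((size_t)g.sp() * n + (size_t)g.ph() * w + h);
      }
    }
  return out;
}

static mat subsample2_back(const mat &dY, const Geom &g, const Geom &g2) {
  mat out(dY.n_rows, g.cols(), arma::fill::zeros);
  for (int n = 0; n < g.N; ++n)
    for (int w2 = 1; w2 <= g2.W; ++w2) {
      const int w = 2 * w2 - 1;
      for (int h2 = 1; h2 <= g2.H; ++h2) {
        const int h = 2 * h2 - 1;
        out.col((size_t)g.sp() * n + (size_t)g.ph() * w + h) =
            dY.col((size_t)g2.sp() * n + (size_t)g2.ph() * w2 + h2);
      }
    }
  return out;
}

// padded map at (H, W) -> padded map at (2H, 2W), nearest neighbour
static mat upsample2(const mat &X, const Geom &g, Geom &g2) {
  g2 = Geom{2 * g.H, 2 * g.W, g.N};
  mat out(X.n_rows, g2.cols(), arma::fill::zeros);
  for (int n = 0; n < g.N; ++n)
    for (int w2 = 1; w2 <= g2.W; ++w2) {
      const int w = (w2 + 1) / 2;
      for (int h2 = 1; h2 <= g2.H; ++h2) {
        const int h = (h2 + 1) / 2;
        out.col((size_t)g2.sp() * n + (size_t)g2.ph() * w2 + h2) =
            X.col((size_t)g.sp() * n + (size_t)g.ph() * w + h);
      }
    }
  return out;
}

static mat upsample2_back(const mat &dY, const Geom &g, const Geom &g2) {
  mat out(dY.n_rows, g.cols(), arma::fill::zeros);
  for (int n = 0; n < g2.N; ++n)
    for (int w2 = 1; w2 <= g2.W; ++w2) {
      const int w = (w2 + 1) / 2;
      for (int h2 = 1; h2 <= g2.H; ++h2) {
        const int h = (h2 + 1) / 2;
        out.col((size_t)g.sp() * n + (size_t)g.ph() * w + h) +=
            dY.col((size_t)g2.sp() * n + (size_t)g2.ph() * w2 + h2);
      }
    }
  return out;
}

// (P, N) image batch (h fastest, no pad) -> padded single-channel map
static mat pad_in(const mat &X, const Geom &g) {
  mat out(1, g.cols(), arma::fill::zeros);
  for (int n = 0; n < g.N; ++n) {
    const double *src = X.colptr(n);
    for (int w = 1; w <= g.W; ++w)
      for (int h = 0; h < g.H; ++h)
        out.at(0, (size_t)g.sp() * n + (size_t)g.ph() * w + 1 + h) =
            src[h + (size_t)g.H * (w - 1)];
  }
  return out;
}

// flatten padded map -> dense feature matrix (C*H*W, N), channel-major
static mat unpad_flat(const mat &X, const Geom &g) {
  const int C = X.n_rows;
  mat out((size_t)C * g.H * g.W, g.N);
  for (int n = 0; n < g.N; ++n)
    for (int w = 1; w <= g.W; ++w)
      for (int h = 1; h <= g.H; ++h) {
        const double *src = X.colptr((size_t)g.sp() * n + (size_t)g.ph() * w + h);
        double *dst = out.colptr(n) +
                      (size_t)C * ((h - 1) + (size_t)g.H * (w - 1));
        for (int c = 0; c < C; ++c) dst[c] = src[c];
      }
  return out;
}

static mat pad_unflat(const mat &F, int C, const Geom &g) {
  mat out(C, g.cols(), arma::fill::zeros);
  for (int n = 0; n < g.N; ++n)
    for (int w = 1; w <= g.W; ++w)
      for (int h = 1; h <= g.H; ++h) {
        double *dst = out.colptr((size_t)g.sp() * n + (size_t)g.ph() * w + h);
        const double *src = F.colptr(n) +
                            (size_t)C * ((h - 1) + (size_t)g.H * (w - 1));
        for (int c = 0; c < C; ++c) dst[c] = src[c];
      }
  return out;
}

struct Arch {
  int H, W, D, nl;
  std::vector<int> enc;
  double leaky;
};

static Arch read_arch(const List &arch) {
  Arch a;
  a.H = as<int>(arch["H"]);
  a.W = as<int>(arch["W"]);
  a.D = as<int>(arch["D"]);
  a.enc = as<std::vector<int>>(arch["enc_channels"]);
  a.nl = a.enc.size();
  a.leaky = as<double>(arch["leaky"]);
  return a;
}

struct Cache {
  std::vector<mat> enc_in;    // padded inputs of each encoder conv
  std::vector<Geom> enc_gin;  // geometry of those inputs
  std::vector<mat> enc_act;   // padded post-activation (pre-subsample)
  std::vector<mat> enc_sub;   // padded subsampled maps
  std::vector<Geom> enc_gout;
  std::vector<mat> dec_up;    // padded upsampled inputs of each decoder conv
  std::vector<mat> dec_act;   // padded post-activation decoder maps
  std::vector<Geom> dec_g;    // geometry after each decoder conv
  mat flat, Mu, Lv, Z, G0p, Xhat;
  Geom g0;
  int C0;
};

static void enc_forward(const mat &X, const List &p, const Arch &a, Cache &cc,
                        bool keep) {
  List enc = p["enc"];
  Geom g{a.H, a.W, (int)X.n_cols};
  mat A = pad_in(X, g);
  for (int l = 0; l < a.nl; ++l) {
    List lay = enc[l];
    mat Wk = lay["W"];
    vec b = lay["b"];
    if (keep) { cc.enc_in.push_back(A); cc.enc_gin.push_back(g); }
    mat Y(Wk.n_cols, g.cols(), arma::fill::zeros);
    conv9(A, Wk, Y, g);
    finish_layer(Y, b, g, 0.0);  // ReLU
    if (keep) cc.enc_act.push_back(Y);
    Geom g2;
    A = subsample2(Y, g, g2);
    g = g2;
    if (keep) { cc.enc_sub.push_back(A); cc.enc_gout.push_back(g); }
    if (!keep && l == a.nl - 1) cc.enc_gout.push_back(g);
  }
  if (!keep) cc.enc_gout.back() = g;
  cc.flat = unpad_flat(A, g);
  mat Wm = p["Wm"], Wv = p["Wv"];
  vec bm = p["bm"], bv = p["bv"];
  cc.Mu = Wm.t() * cc.flat;
  cc.Mu.each_col() += bm;
  cc.Lv = Wv.t() * cc.flat;
  cc.Lv.each_col() += bv;
  cc.Lv = arma::clamp(cc.Lv, -10.0, 10.0);
}

static void dec_forward(const mat &Z, const List &p, const Arch &a, Cache &cc,
                        bool keep) {
  const int N = Z.n_cols;
  const double sl = a.leaky;
  const int nl = a.nl;
  mat U0 = p["U0"];
  vec c0 = p["c0"];
  Geom g{a.H >> nl, a.W >> nl, N};
  mat G = U0.t() * Z;
  G.each_col() += c0;
  for (size_t i = 0; i < G.n_elem; ++i)
    if (G[i] < 0) G[i] *= sl;
  cc.C0 = G.n_rows / ((size_t)g.H * g.W);
  cc.G0p = pad_unflat(G, cc.C0, g);
  cc.g0 = g;
  List dec = p["dec"];
  mat A = cc.G0p;
  for (int l = 0; l < nl; ++l) {
    List lay = dec[l];
    mat Wk = lay["W"];
    vec b = lay["b"];
    Geom g2;
    mat up = upsample2(A, g, g2);
    g = g2;
    if (keep) cc.dec_up.push_back(up);
    mat Y(Wk.n_cols, g.cols(), arma::fill::zeros);
    conv9(up, Wk, Y, g);
    finish_layer(Y, b, g, sl);
    A = Y;
    if (keep) { cc.dec_act.push_back(A); cc.dec_g.push_back(g); }
  }
  if (!keep) { cc.dec_act.push_back(A); cc.dec_g.push_back(g); }
  List outl = p["out"];
  mat Wo = outl["W"];
  vec bo = outl["b"];
  mat Y(1, g.cols(), arma::fill::zeros);
  conv9(A, Wo, Y, g);
  // bias + sigmoid on interior, then unpad to (P, N)
  mat Xhat((size_t)g.H * g.W, N);
  for (int n = 0; n < N; ++n)
    for (int w = 1; w <= g.W; ++w)
      for (int h = 1; h <= g.H; ++h) {
        double v = Y.at(0, (size_t)g.sp() * n + (size_t)g.ph() * w + h) + bo[0];
        Xhat.at((h - 1) + (size_t)g.H * (w - 1), n) = 1.0 / (1.0 + std::exp(-v));
      }
  cc.Xhat = Xhat;
}

// [[Rcpp::export]]
List cvae_encode_cpp(const arma::mat &X, const List &params,
                     const List &arch) {
  Arch a = read_arch(arch);
  Cache cc;
  enc_forward(X, params, a, cc, false);
  return List::create(Named("Mu") = cc.Mu, Named("Lv") = cc.Lv);
}

// [[Rcpp::export]]
arma::mat cvae_decode_cpp(const arma::mat &Z, const List &params,
                          const List &arch) {
  Arch a = read_arch(arch);
  Cache cc;
  dec_forward(Z, params, a, cc, false);
  return cc.Xhat;
}

// [[Rcpp::export]]
List cvae_step_cpp(const arma::mat &X, const List &params, const List &arch,
                   const arma::mat &eps, double beta) {
  Arch a = read_arch(arch);
  const int N = X.n_cols;
  const double sl = a.leaky;
  const int nl = a.nl;
  Cache cc;
  enc_forward(X, params, a, cc, true);
  cc.Z = cc.Mu + arma::exp(0.5 * cc.Lv) % eps;
  dec_forward(cc.Z, params, a, cc, true);

  const double mse = arma::accu(arma::square(X - cc.Xhat)) / N;
  const double kl =
      arma::accu(0.5 *
                 (arma::exp(cc.Lv) + arma::square(cc.Mu) - 1.0 - cc.Lv)) /
      N;

  // ---- output conv backward ----
  Geom g = cc.dec_g[nl - 1];
  mat dXhat = (2.0 / N) * (cc.Xhat - X) % cc.Xhat % (1.0 - cc.Xhat);
  mat dPo = pad_unflat(dXhat, 1, g);  // (1, cols), pads zero
  List outl = params["out"];
  mat Wo = outl["W"];
  mat dWo(arma::size(Wo), arma::fill::zeros);
  mat dA(cc.dec_act[nl - 1].n_rows, g.cols(), arma::fill::zeros);
  conv9_back(cc.dec_act[nl - 1], Wo, dPo, dA, dWo, g);
  vec dbo(1);
  dbo[0] = arma::accu(dPo);

  // ---- decoder conv stack ----
  List dec = params["dec"];
  List g_dec(nl);
  for (int l = nl - 1; l >= 0; --l) {
    g = cc.dec_g[l];
    // dA holds grad wrt post-activation map of layer l (pads may be dirty)
    mat dZl = act_back(dA, cc.dec_act[l], sl);
    mat Wl = as<List>(dec[l])["W"];
    mat dWl(arma::size(Wl), arma::fill::zeros);
    mat dUp(cc.dec_up[l].n_rows, g.cols(), arma::fill::zeros);
    conv9_back(cc.dec_up[l], Wl, dZl, dUp, dWl, g);
    vec dbl(Wl.n_cols, arma::fill::zeros);
    interior(g, [&](size_t c0, size_t len) {
      for (size_t j = 0; j < len; ++j) dbl += dZl.col(c0 + j);
    });
    g_dec[l] = List::create(Named("W") = dWl, Named("b") = dbl);
    Geom gp = (l == 0) ? cc.g0 : cc.dec_g[l - 1];
    dA = upsample2_back(dUp, gp, g);
  }

  // ---- decoder dense ----
  mat dG0flat = unpad_flat(dA, cc.g0);
  mat G0flat = unpad_flat(cc.G0p, cc.g0);
  mat dG0 = act_back(dG0flat, G0flat, sl);
  mat U0 = params["U0"];
  mat dU0 = cc.Z * dG0.t();
  vec dc0 = arma::sum(dG0, 1);
  mat dZlat = U0 * dG0;

  // ---- KL + reparameterization ----
  mat lv_mask(arma::size(cc.Lv));
  for (size_t i = 0; i < cc.Lv.n_elem; ++i)
    lv_mask[i] = (cc.Lv[i] > -10.0 && cc.Lv[i] < 10.0) ? 1.0 : 0.0;
  mat dMu = dZlat + beta * cc.Mu / N;
  mat dLv = (dZlat % eps % (0.5 * arma::exp(0.5 * cc.Lv)) +
             beta * 0.5 * (arma::exp(cc.Lv) - 1.0) / N) %
            lv_mask;

  // ---- encoder heads ----
  mat Wm = params["Wm"], Wv = params["Wv"];
  mat dWm = cc.flat * dMu.t();
  vec dbm = arma::sum(dMu, 1);
  mat dWv = cc.flat * dLv.t();
  vec dbv = arma::sum(dLv, 1);
  mat dFlat = Wm * dMu + Wv * dLv;

  // ---- encoder conv stack ----
  List enc = params["enc"];
  List g_enc(nl);
  mat dSub = pad_unflat(dFlat, a.enc[nl - 1], cc.enc_gout[nl - 1]);
  for (int l = nl - 1; l >= 0; --l) {
    Geom gi = cc.enc_gin[l];          // geometry of layer input / activation
    Geom go = cc.enc_gout[l];         // geometry after subsample
    mat dY = subsample2_back(dSub, gi, go);
    mat dZe = act_back(dY, cc.enc_act[l], 0.0);
    mat Wl = as<List>(enc[l])["W"];
    mat dWl(arma::size(Wl), arma::fill::zeros);
    mat dIn(cc.enc_in[l].n_rows, gi.cols(), arma::fill::zeros);
    conv9_back(cc.enc_in[l], Wl, dZe, dIn, dWl, gi);
    vec dbl(Wl.n_cols, arma::fill::zeros);
    interior(gi, [&](size_t c0, size_t len) {
      for (size_t j = 0; j < len; ++j) dbl += dZe.col(c0 + j);
    });
    g_enc[l] = List::create(Named("W") = dWl, Named("b") = dbl);
    if (l > 0) {
      // dIn pads may be dirty: re-extract interior before next level
      dSub = pad_unflat(unpad_flat(dIn, gi), dIn.n_rows, gi);
      // note: next iteration's go is enc_gout[l-1] == gi
    }
  }

  List grads = List::create(
      Named("enc") = g_enc, Named("Wm") = dWm, Named("bm") = dbm,
      Named("Wv") = dWv, Named("bv") = dbv, Named("U0") = dU0,
      Named("c0") = dc0, Named("dec") = g_dec,
      Named("out") = List::create(Named("W") = dWo, Named("b") = dbo));
  return List::create(Named("mse") = mse, Named("kl") = kl,
                      Named("grads") = grads);
}
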