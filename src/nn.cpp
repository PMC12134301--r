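// Compact convolutional-network engine for the patient-specific conditional
// GAN: a UNet generator (4x4 stride-2 encoder/decoder with skip connections)
// and a PatchGAN discriminator, with hand-derived backprop. im2col/col2im +
// GEMM convolutions; non-affine instance normalisation on inner layers;
// LeakyReLU(0.2) encoder / ReLU decoder activations; sigmoid outputs.
//
// Feature maps are arma::cube (rows x cols x channels); output positions are
// flattened column-major (p = col*Ho + row). Weights: W in R^{Cout x (Cin k^2)}
// for convolutions; transposed convolutions store the weight of the adjoint
// convolution, W in R^{Cin x (Cout k^2)}.
#include <RcppArmadillo.h>
using namespace Rcpp;

static const double SCORE_EPS = 1e-7;  // clamp for log-scores at exactly 0/1
static const double IN_EPS = 1e-5;

struct LayerSpec {
  int cin, cout, k, s, p;
  bool transposed;
  bool norm;      // instance norm after the (de)convolution
  int act;        // 0 none, 1 lrelu(0.2), 2 relu, 3 sigmoid
};

// ---------------------------------------------------------------- im2col ---
static arma::mat im2col(const arma::cube& X, int k, int s, int p,
                        int& Ho, int& Wo) {
  const int H = X.n_rows, W = X.n_cols, C = X.n_slices;
  Ho = (H + 2 * p - k) / s + 1;
  Wo = (W + 2 * p - k) / s + 1;
  arma::mat cols(C * k * k, Ho * Wo, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int ki = 0; ki < k; ++ki)        // kernel row
      for (int kj = 0; kj < k; ++kj) {    // kernel col
        const int row = (c * k + ki) * k + kj;
        for (int ox = 0; ox < Wo; ++ox) {
          const int ix = ox * s - p + kj;
          if (ix < 0 || ix >= W) continue;
          for (int oy = 0; oy < Ho; ++oy) {
            const int iy = oy * s - p + ki;
            if (iy < 0 || iy >= H) continue;
            cols(row, ox * Ho + oy) = X(iy, ix, c);
          }
        }
      }
  return cols;
}

static arma::cube col2im(const arma::mat& cols, int H, int W, int C,
                         int k, int s, int p) {
  const int Ho = (H + 2 * p - k) / s + 1;
  const int Wo = (W + 2 * p - k) / s + 1;
  arma::cube X(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int ki = 0; ki < k; ++ki)
      for (int kj = 0; kj < k; ++kj) {
        const int row = (c * k + ki) * k + kj;
        for (int ox = 0; ox < Wo; ++ox) {
          const int ix = ox * s - p + kj;
          if (ix < 0 || ix >= W) continue;
          for (int oy = 0; oy < Ho; ++oy) {
            const int iy = oy * s - p + ki;
            if (iy < 0 || iy >= H) continue;
            X(iy, ix, c) += cols(row, ox * Ho + oy);
          }
        }
      }
  return X;
}

static arma::mat cube_to_mat(const arma::cube& X) {
  // channels x positions (column-major positions)
  arma::mat M(X.n_slices, X.n_rows * X.n_cols);
  for (arma::uword c = 0; c < X.n_slices; ++c) {
    const arma::mat& sl = X.slice(c);
    M.row(c) = arma::vectorise(sl).t();
  }
  return M;
}

static arma::cube mat_to_cube(const arma::mat& M, int H, int W) {
  arma::cube X(H, W, M.n_rows);
  for (arma::uword c = 0; c < M.n_rows; ++c)
    X.slice(c) = arma::reshape(M.row(c), H, W);
  return X;
}

// ------------------------------------------------------------ layer fwd ----
struct LayerCache {
  arma::cube in;        // layer input (pre conv)
  arma::mat cols;       // im2col of input (conv) or of dOut (unused fwd)
  arma::cube pre_norm;  // conv output before norm
  arma::cube normed;    // after norm (pre activation)
  arma::cube out;       // after activation
  arma::vec mu, sd;     // instance-norm stats per channel
};

static arma::cube activate(const arma::cube& Z, int act) {
  arma::cube A = Z;
  if (act == 1) A.transform([](double v) { return v > 0 ? v : 0.2 * v; });
  else if (act == 2) A.transform([](double v) { return v > 0 ? v : 0.0; });
  else if (act == 3) A.transform([](double v) { return 1.0 / (1.0 + std::exp(-v)); });
  return A;
}

static arma::cube act_backward(const arma::cube& dA, const arma::cube& Z,
                               const arma::cube& A, int act) {
  arma::cube dZ = dA;
  if (act == 1) {
    for (arma::uword i = 0; i < Z.n_elem; ++i)
      if (Z(i) <= 0) dZ(i) *= 0.2;
  } else if (act == 2) {
    for (arma::uword i = 0; i < Z.n_elem; ++i)
      if (Z(i) <= 0) dZ(i) = 0;
  } else if (act == 3) {
    for (arma::uword i = 0; i < Z.n_elem; ++i)
      dZ(i) *= A(i) * (1 - A(i));
  }
  return dZ;
}

static arma::cube inorm_forward(const arma::cube& Z, arma::vec& mu, arma::vec& sd) {
  arma::cube N = Z;
  mu.set_size(Z.n_slices);
  sd.set_size(Z.n_slices);
  for (arma::uword c = 0; c < Z.n_slices; ++c) {
    const double m = arma::accu(Z.slice(c)) / Z.slice(c).n_elem;
    arma::mat cc = Z.slice(c) - m;
    const double v = arma::accu(cc % cc) / cc.n_elem;
    const double s = std::sqrt(v + IN_EPS);
    mu(c) = m;
    sd(c) = s;
    N.slice(c) = cc / s;
  }
  return N;
}

static arma::cube inorm_backward(const arma::cube& dN, const arma::cube& N,
                                 const arma::vec& sd) {
  arma::cube dZ = dN;
  for (arma::uword c = 0; c < dN.n_slices; ++c) {
    const double mdy = arma::accu(dN.slice(c)) / dN.slice(c).n_elem;
    const double mdyx = arma::accu(dN.slice(c) % N.slice(c)) / dN.slice(c).n_elem;
    dZ.slice(c) = (dN.slice(c) - mdy - N.slice(c) * mdyx) / sd(c);
  }
  return dZ;
}

static arma::cube layer_forward(const LayerSpec& L, const arma::mat& Wt,
                                const arma::vec& b, const arma::cube& X,
                                LayerCache& cache) {
  cache.in = X;
  arma::cube Z;
  if (!L.transposed) {
    int Ho, Wo;
    cache.cols = im2col(X, L.k, L.s, L.p, Ho, Wo);
    arma::mat Y = Wt * cache.cols;
    Y.each_col() += b;
    Z = mat_to_cube(Y, Ho, Wo);
  } else {
    const int H = X.n_rows * L.s, W = X.n_cols * L.s;
    arma::mat Zm = cube_to_mat(X);
    Z = col2im(Wt.t() * Zm, H, W, L.cout, L.k, L.s, L.p);
    for (int c = 0; c < L.cout; ++c) Z.slice(c) += b(c);
  }
  cache.pre_norm = Z;
  if (L.norm) Z = inorm_forward(Z, cache.mu, cache.sd);
  cache.normed = Z;
  cache.out = activate(Z, L.act);
  return cache.out;
}

static arma::cube layer_backward(const LayerSpec& L, const arma::mat& Wt,
                                 const LayerCache& cache, const arma::cube& dOut,
                                 arma::mat& dW, arma::vec& db) {
  arma::cube dZ = act_backward(dOut, cache.normed, cache.out, L.act);
  if (L.norm) dZ = inorm_backward(dZ, cache.normed, cache.sd);
  if (!L.transposed) {
    arma::mat dYm = cube_to_mat(dZ);
    dW = dYm * cache.cols.t();
    db = arma::sum(dYm, 1);
    arma::mat dcols = Wt.t() * dYm;
    return col2im(dcols, cache.in.n_rows, cache.in.n_cols, L.cin, L.k, L.s, L.p);
  } else {
    int Ho, Wo;
    arma::mat cols_d = im2col(dZ, L.k, L.s, L.p, Ho, Wo);
    arma::mat Zm = cube_to_mat(cache.in);
    dW = Zm * cols_d.t();
    db.set_size(L.cout);
    for (int c = 0; c < L.cout; ++c) db(c) = arma::accu(dZ.slice(c));
    return mat_to_cube(Wt * cols_d, cache.in.n_rows, cache.in.n_cols);
  }
}

// ------------------------------------------------------ network assembly ---
static int chan(int base, int level) {
  int c = base;
  for (int i = 1; i < level; ++i) c = std::min(2 * c, 8 * base);
  return c;
}

static std::vector<LayerSpec> unet_spec(int base, int depth, int use_norm = 1) {
  std::vector<LayerSpec> L;
  for (int i = 1; i <= depth; ++i) {
    LayerSpec s;
    s.cin = (i == 1) ? 1 : chan(base, i - 1);
    s.cout = chan(base, i);
    s.k = 4; s.s = 2; s.p = 1;
    s.transposed = false;
    s.norm = use_norm && (i > 1);
    s.act = 1;  // LeakyReLU
    L.push_back(s);
  }
  for (int i = depth; i >= 1; --i) {
    LayerSpec s;
    s.cin = (i == depth) ? chan(base, depth)
                         : chan(base, i) /* dec out of i+1 */ + chan(base, i) /* skip */;
    s.cout = (i > 1) ? chan(base, i - 1) : 1;
    s.k = 4; s.s = 2; s.p = 1;
    s.transposed = true;
    s.norm = use_norm && (i > 1);
    s.act = (i > 1) ? 2 : 3;  // ReLU inner, sigmoid output
    L.push_back(s);
  }
  return L;
}

static std::vector<LayerSpec> patchgan_spec(int base, int levels, int use_norm = 1) {
  std::vector<LayerSpec> L;
  int cin = 2;
  for (int i = 1; i < levels; ++i) {
    LayerSpec s;
    s.cin = cin;
    s.cout = chan(base, i);
    s.k = 4; s.s = 2; s.p = 1;
    s.transposed = false;
    s.norm = use_norm && (i > 1);
    s.act = 1;
    L.push_back(s);
    cin = s.cout;
  }
  LayerSpec f;
  f.cin = cin; f.cout = 1; f.k = 3; f.s = 1; f.p = 1;
  f.transposed = false; f.norm = false; f.act = 3;
  L.push_back(f);
  return L;
}

// parameter shapes for R-side initialisation: list of c(nrow, ncol) per W
// interleaved with bias lengths
// [[Rcpp::export(name = ".cpp_gan_shapes")]]
List cpp_gan_shapes(int base, int depth, int patch_levels, int use_norm) {
  std::vector<LayerSpec> G = unet_spec(base, depth, use_norm);
  std::vector<LayerSpec> D = patchgan_spec(base, patch_levels, use_norm);
  auto pack = [](const std::vector<LayerSpec>& S) {
    List out;
    for (size_t i = 0; i < S.size(); ++i) {
      const LayerSpec& s = S[i];
      int wr = s.transposed ? s.cin : s.cout;
      int wc = s.transposed ? s.cout * s.k * s.k : s.cin * s.k * s.k;
      int bl = s.cout;
      out.push_back(List::create(_["w"] = IntegerVector::create(wr, wc),
                                 _["b"] = bl,
                                 _["fan_in"] = s.cin * s.k * s.k));
    }
    return out;
  };
  return List::create(_["g"] = pack(G), _["d"] = pack(D));
}

struct Net {
  std::vector<LayerSpec> spec;
  std::vector<arma::mat> W;
  std::vector<arma::vec> b;
};

static Net unpack_net(const std::vector<LayerSpec>& spec, const List& params) {
  Net net;
  net.spec = spec;
  for (size_t i = 0; i < spec.size(); ++i) {
    net.W.push_back(as<arma::mat>(params[2 * i]));
    net.b.push_back(as<arma::vec>(params[2 * i + 1]));
  }
  return net;
}

static arma::cube concat_ch(const arma::cube& A, const arma::cube& B) {
  arma::cube C(A.n_rows, A.n_cols, A.n_slices + B.n_slices);
  C.slices(0, A.n_slices - 1) = A;
  C.slices(A.n_slices, C.n_slices - 1) = B;
  return C;
}

struct UnetCache {
  std::vector<LayerCache> caches;  // one per layer, in spec order
};

static arma::cube unet_forward_one(const Net& G, const arma::mat& x,
                                   UnetCache& uc) {
  const int depth = (int)G.spec.size() / 2;
  uc.caches.resize(G.spec.size());
  std::vector<arma::cube> enc(depth);
  arma::cube h(x.n_rows, x.n_cols, 1);
  h.slice(0) = x;
  for (int i = 0; i < depth; ++i) {
    h = layer_forward(G.spec[i], G.W[i], G.b[i], h, uc.caches[i]);
    enc[i] = h;
  }
  for (int j = 0; j < depth; ++j) {
    const int li = depth + j;        // layer index
    const int lvl = depth - j;       // decoder level
    arma::cube in = (lvl == depth) ? enc[depth - 1]
                                   : concat_ch(h, enc[lvl - 1]);
    h = layer_forward(G.spec[li], G.W[li], G.b[li], in, uc.caches[li]);
  }
  return h;  // 1-channel sigmoid output
}

// backward through the UNet given d(output); accumulates into grads
static void unet_backward_one(const Net& G, const UnetCache& uc,
                              const arma::cube& dOut,
                              std::vector<arma::mat>& gW,
                              std::vector<arma::vec>& gb) {
  const int depth = (int)G.spec.size() / 2;
  std::vector<arma::cube> denc(depth);  // accumulated grads for encoder outputs
  arma::cube d = dOut;
  for (int j = depth - 1; j >= 0; --j) {
    const int li = depth + j;
    const int lvl = depth - j;
    arma::mat dW;
    arma::vec db;
    arma::cube din = layer_backward(G.spec[li], G.W[li], uc.caches[li], d, dW, db);
    gW[li] += dW;
    gb[li] += db;
    if (lvl == depth) {
      denc[depth - 1] = din;  // bottleneck: input was enc[depth-1], no concat
    } else {
      // input was concat(prev_dec_out, enc[lvl-1])
      const int c1 = din.n_slices - G.spec[lvl - 1].cout;  // prev dec channels
      arma::cube d_prev = din.slices(0, c1 - 1);
      arma::cube d_skip = din.slices(c1, din.n_slices - 1);
      if (denc[lvl - 1].n_elem == 0) denc[lvl - 1] = d_skip;
      else denc[lvl - 1] += d_skip;
      d = d_prev;
    }
  }
  // encoder backward, deepest first, merging skip-connection grads
  arma::cube dcur = denc[depth - 1];
  for (int i = depth - 1; i >= 0; --i) {
    if (i < depth - 1 && denc[i].n_elem > 0) dcur += denc[i];
    arma::mat dW;
    arma::vec db;
    dcur = layer_backward(G.spec[i], G.W[i], uc.caches[i], dcur, dW, db);
    gW[i] += dW;
    gb[i] += db;
  }
}

static arma::cube disc_forward_one(const Net& D, const arma::mat& x,
                                   const arma::mat& y, UnetCache& dc) {
  dc.caches.resize(D.spec.size());
  arma::cube h(x.n_rows, x.n_cols, 2);
  h.slice(0) = x;
  h.slice(1) = y;
  for (size_t i = 0; i < D.spec.size(); ++i)
    h = layer_forward(D.spec[i], D.W[i], D.b[i], h, dc.caches[i]);
  return h;  // patch scores in (0,1)
}

// backward through D; returns grad w.r.t. the second input channel (the mask)
static arma::mat disc_backward_one(const Net& D, const UnetCache& dc,
                                   const arma::cube& dScore,
                                   std::vector<arma::mat>& gW,
                                   std::vector<arma::vec>& gb,
                                   bool need_input_grad) {
  arma::cube d = dScore;
  for (int i = (int)D.spec.size() - 1; i >= 0; --i) {
    arma::mat dW;
    arma::vec db;
    d = layer_backward(D.spec[i], D.W[i], dc.caches[i], d, dW, db);
    gW[i] += dW;
    gb[i] += db;
  }
  if (need_input_grad) return d.slice(1);
  return arma::mat();
}

static std::vector<arma::mat> zeros_like_W(const Net& n) {
  std::vector<arma::mat> g;
  for (size_t i = 0; i < n.W.size(); ++i)
    g.push_back(arma::mat(n.W[i].n_rows, n.W[i].n_cols, arma::fill::zeros));
  return g;
}
static std::vector<arma::vec> zeros_like_b(const Net& n) {
  std::vector<arma::vec> g;
  for (size_t i = 0; i < n.b.size(); ++i)
    g.push_back(arma::vec(n.b[i].n_elem, arma::fill::zeros));
  return g;
}

static List pack_grads(const std::vector<arma::mat>& gW,
                       const std::vector<arma::vec>& gb) {
  List out(2 * gW.size());
  for (size_t i = 0; i < gW.size(); ++i) {
    out[2 * i] = wrap(gW[i]);
    out[2 * i + 1] = wrap(gb[i]);
  }
  return out;
}

// ------------------------------------------------------------- exports -----
// generator inference over a batch (slices of x are samples)
// [[Rcpp::export(name = ".cpp_unet_predict")]]
arma::cube cpp_unet_predict(const List& gparams, const arma::cube& x,
                            int base, int depth, int use_norm) {
  Net G = unpack_net(unet_spec(base, depth, use_norm), gparams);
  arma::cube out(x.n_rows, x.n_cols, x.n_slices);
  for (arma::uword s = 0; s < x.n_slices; ++s) {
    UnetCache uc;
    out.slice(s) = unet_forward_one(G, x.slice(s), uc).slice(0);
  }
  return out;
}

// discriminator patch scores for one (x, y) pair
// [[Rcpp::export(name = ".cpp_disc_predict")]]
arma::mat cpp_disc_predict(const List& dparams, const arma::mat& x,
                           const arma::mat& y, int base, int patch_levels,
                           int use_norm) {
  Net D = unpack_net(patchgan_spec(base, patch_levels, use_norm), dparams);
  UnetCache dc;
  return disc_forward_one(D, x, y, dc).slice(0);
}

// gradients of mean|y - G(x)| alone over a batch (L1-regression reference)
// [[Rcpp::export(name = ".cpp_unet_l1_grads")]]
List cpp_unet_l1_grads(const List& gparams, const arma::cube& x,
                       const arma::cube& y, int base, int depth, int use_norm) {
  Net G = unpack_net(unet_spec(base, depth, use_norm), gparams);
  std::vector<arma::mat> gW = zeros_like_W(G);
  std::vector<arma::vec> gb = zeros_like_b(G);
  double l1 = 0;
  const int n = x.n_slices;
  for (int s = 0; s < n; ++s) {
    UnetCache uc;
    arma::cube g = unet_forward_one(G, x.slice(s), uc);
    arma::mat diff = g.slice(0) - y.slice(s);
    l1 += arma::accu(arma::abs(diff)) / diff.n_elem;
    arma::cube dg(g.n_rows, g.n_cols, 1);
    dg.slice(0) = arma::sign(diff) / (double)diff.n_elem / (double)n;
    unet_backward_one(G, uc, dg, gW, gb);
  }
  List out = pack_grads(gW, gb);
  out.attr("l1") = l1 / n;
  return out;
}

// full cGAN gradients for one batch: discriminator loss
//   loss_D = -(mean log D(x,y) + mean log(1 - D(x,G(x))))   (fake detached)
// and non-saturating generator loss
//   loss_G = -mean log D(x,G(x)) + lambda * mean|y - G(x)|.
// [[Rcpp::export(name = ".cpp_cgan_batch_grads")]]
List cpp_cgan_batch_grads(const List& gparams, const List& dparams,
                          const arma::cube& x, const arma::cube& y,
                          double lambda, int base, int depth,
                          int patch_levels, int use_norm) {
  Net G = unpack_net(unet_spec(base, depth, use_norm), gparams);
  Net D = unpack_net(patchgan_spec(base, patch_levels, use_norm), dparams);
  std::vector<arma::mat> gW = zeros_like_W(G), dW = zeros_like_W(D);
  std::vector<arma::vec> gb = zeros_like_b(G), db = zeros_like_b(D);
  double loss_d = 0, adv = 0, l1 = 0;
  const int n = x.n_slices;
  for (int s = 0; s < n; ++s) {
    UnetCache gc;
    arma::cube g = unet_forward_one(G, x.slice(s), gc);
    // --- discriminator update terms ---
    UnetCache dcr, dcf;
    arma::cube sr = disc_forward_one(D, x.slice(s), y.slice(s), dcr);
    arma::cube sf = disc_forward_one(D, x.slice(s), g.slice(0), dcf);
    const double P = sr.n_elem;
    arma::cube src = arma::clamp(sr, SCORE_EPS, 1 - SCORE_EPS);
    arma::cube sfc = arma::clamp(sf, SCORE_EPS, 1 - SCORE_EPS);
    loss_d += -(arma::accu(arma::log(src)) + arma::accu(arma::log(1 - sfc))) / P;
    adv += -arma::accu(arma::log(sfc)) / P;
    arma::mat diff = g.slice(0) - y.slice(s);
    l1 += arma::accu(arma::abs(diff)) / diff.n_elem;
    // D grads: real term d/ds(-log s) = -1/s; fake term d/ds(-log(1-s)) = 1/(1-s)
    const double invn = 1.0 / n;
    arma::cube dsr = src, dsf = sfc, dsf_g = sfc;
    dsr.transform([P, invn](double v) { return -invn / (v * P); });
    dsf.transform([P, invn](double v) { return invn / ((1.0 - v) * P); });
    dsf_g.transform([P, invn](double v) { return -invn / (v * P); });
    disc_backward_one(D, dcr, dsr, dW, db, false);
    disc_backward_one(D, dcf, dsf, dW, db, false);
    // G grads: adversarial d/ds(-log s) = -1/s through the fake pass
    // (recompute backward through dcf with D grads discarded)
    std::vector<arma::mat> tmpW = zeros_like_W(D);
    std::vector<arma::vec> tmpb = zeros_like_b(D);
    arma::mat dg_adv = disc_backward_one(D, dcf, dsf_g, tmpW, tmpb, true);
    arma::cube dg(g.n_rows, g.n_cols, 1);
    dg.slice(0) = dg_adv + lambda * arma::sign(diff) / (double)diff.n_elem / n;
    unet_backward_one(G, gc, dg, gW, gb);
  }
  return List::create(_["g_grads"] = pack_grads(gW, gb),
                      _["d_grads"] = pack_grads(dW, db),
                      _["loss_d"] = loss_d / n,
                      _["adv"] = adv / n,
                      _["l1"] = l1 / n,
                      _["loss_g"] = adv / n + lambda * l1 / n);
}
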