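// Masked multi-head attention encoder with a recurrent master node:
// forward pass, exact backward pass (for Adam training), and attention
// gradients (for relevance propagation). The master node occupies row 0;
// its output is the graph embedding of the snapshot and is fed to the next
// snapshot's input row 0 within a temporal window.
//
// Post-norm Transformer layer:
//   O  = MultiHeadAttention(H, mask) ; H1 = LN1(H + O)
//   F  = ReLU(H1 W1 + b1) W2 + b2   ; H2 = LN2(H1 + F)
// Attention logits are set to -Inf wherever the mask is 0, so masked
// attention weights are exactly zero after the softmax.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

static const double LN_EPS = 1e-5;

struct Layer {
  mat Wq, Wk, Wv, Wo, W1, W2;
  vec ln1g, ln1b, b1, b2, ln2g, ln2b;
};

struct Params {
  vec z0;
  mat Wf; vec bf;
  std::vector<Layer> layers;
  mat Wh1; vec bh1; mat Wh2; vec bh2; mat Wh3; vec bh3;
  int n_heads;
};

static Layer layer_from_list(const Rcpp::List& l) {
  Layer L;
  L.Wq = Rcpp::as<mat>(l["Wq"]); L.Wk = Rcpp::as<mat>(l["Wk"]);
  L.Wv = Rcpp::as<mat>(l["Wv"]); L.Wo = Rcpp::as<mat>(l["Wo"]);
  L.ln1g = Rcpp::as<vec>(l["ln1g"]); L.ln1b = Rcpp::as<vec>(l["ln1b"]);
  L.W1 = Rcpp::as<mat>(l["W1"]); L.b1 = Rcpp::as<vec>(l["b1"]);
  L.W2 = Rcpp::as<mat>(l["W2"]); L.b2 = Rcpp::as<vec>(l["b2"]);
  L.ln2g = Rcpp::as<vec>(l["ln2g"]); L.ln2b = Rcpp::as<vec>(l["ln2b"]);
  return L;
}

static Params params_from_list(const Rcpp::List& p, int n_heads) {
  Params P;
  P.z0 = Rcpp::as<vec>(p["z0"]);
  P.Wf = Rcpp::as<mat>(p["Wf"]); P.bf = Rcpp::as<vec>(p["bf"]);
  Rcpp::List lay = p["layers"];
  for (int i = 0; i < lay.size(); ++i)
    P.layers.push_back(layer_from_list(lay[i]));
  P.Wh1 = Rcpp::as<mat>(p["Wh1"]); P.bh1 = Rcpp::as<vec>(p["bh1"]);
  P.Wh2 = Rcpp::as<mat>(p["Wh2"]); P.bh2 = Rcpp::as<vec>(p["bh2"]);
  P.Wh3 = Rcpp::as<mat>(p["Wh3"]); P.bh3 = Rcpp::as<vec>(p["bh3"]);
  P.n_heads = n_heads;
  return P;
}

struct Grads {
  vec z0;
  mat Wf; vec bf;
  std::vector<Layer> layers;  // same shapes as params
  mat Wh1; vec bh1; mat Wh2; vec bh2; mat Wh3; vec bh3;
};

static Grads zero_grads(const Params& P) {
  Grads G;
  G.z0 = zeros<vec>(P.z0.n_elem);
  G.Wf = zeros<mat>(size(P.Wf)); G.bf = zeros<vec>(P.bf.n_elem);
  for (size_t i = 0; i < P.layers.size(); ++i) {
    const Layer& L = P.layers[i];
    Layer Z;
    Z.Wq = zeros<mat>(size(L.Wq)); Z.Wk = zeros<mat>(size(L.Wk));
    Z.Wv = zeros<mat>(size(L.Wv)); Z.Wo = zeros<mat>(size(L.Wo));
    Z.ln1g = zeros<vec>(L.ln1g.n_elem); Z.ln1b = zeros<vec>(L.ln1b.n_elem);
    Z.W1 = zeros<mat>(size(L.W1)); Z.b1 = zeros<vec>(L.b1.n_elem);
    Z.W2 = zeros<mat>(size(L.W2)); Z.b2 = zeros<vec>(L.b2.n_elem);
    Z.ln2g = zeros<vec>(L.ln2g.n_elem); Z.ln2b = zeros<vec>(L.ln2b.n_elem);
    G.layers.push_back(Z);
  }
  G.Wh1 = zeros<mat>(size(P.Wh1)); G.bh1 = zeros<vec>(P.bh1.n_elem);
  G.Wh2 = zeros<mat>(size(P.Wh2)); G.bh2 = zeros<vec>(P.bh2.n_elem);
  G.Wh3 = zeros<mat>(size(P.Wh3)); G.bh3 = zeros<vec>(P.bh3.n_elem);
  return G;
}

static Rcpp::List layer_to_list(const Layer& L) {
  return Rcpp::List::create(
    Rcpp::Named("Wq") = L.Wq, Rcpp::Named("Wk") = L.Wk,
    Rcpp::Named("Wv") = L.Wv, Rcpp::Named("Wo") = L.Wo,
    Rcpp::Named("ln1g") = L.ln1g, Rcpp::Named("ln1b") = L.ln1b,
    Rcpp::Named("W1") = L.W1, Rcpp::Named("b1") = L.b1,
    Rcpp::Named("W2") = L.W2, Rcpp::Named("b2") = L.b2,
    Rcpp::Named("ln2g") = L.ln2g, Rcpp::Named("ln2b") = L.ln2b);
}

static Rcpp::List grads_to_list(const Grads& G) {
  Rcpp::List lay(G.layers.size());
  for (size_t i = 0; i < G.layers.size(); ++i) lay[i] = layer_to_list(G.layers[i]);
  return Rcpp::List::create(
    Rcpp::Named("z0") = G.z0,
    Rcpp::Named("Wf") = G.Wf, Rcpp::Named("bf") = G.bf,
    Rcpp::Named("layers") = lay,
    Rcpp::Named("Wh1") = G.Wh1, Rcpp::Named("bh1") = G.bh1,
    Rcpp::Named("Wh2") = G.Wh2, Rcpp::Named("bh2") = G.bh2,
    Rcpp::Named("Wh3") = G.Wh3, Rcpp::Named("bh3") = G.bh3);
}

// ---- layer norm -----------------------------------------------------------

static mat layernorm_forward(const mat& X, const vec& g, const vec& b,
                             mat& xhat, vec& istd) {
  vec mu = mean(X, 1);
  mat Xc = X.each_col() - mu;
  istd = 1.0 / sqrt(mean(square(Xc), 1) + LN_EPS);
  xhat = Xc.each_col() % istd;
  mat Y = xhat.each_row() % g.t();
  Y.each_row() += b.t();
  return Y;
}

static mat layernorm_backward(const mat& dY, const vec& g, const mat& xhat,
                              const vec& istd, vec& dg, vec& db) {
  mat dxh = dY.each_row() % g.t();
  vec m1 = mean(dxh, 1);
  vec m2 = mean(dxh % xhat, 1);
  mat dX = dxh.each_col() - m1;
  dX -= xhat.each_col() % m2;
  dX.each_col() %= istd;
  dg += sum(dY % xhat, 0).t();
  db += sum(dY, 0).t();
  return dX;
}

// ---- single-snapshot encode -----------------------------------------------

struct LayerCache {
  mat Hin, Q, K, V, H1, U, xhat1, xhat2;
  vec istd1, istd2;
  cube A;  // N x N x n_heads attention probabilities
};

struct EncodeCache {
  std::vector<LayerCache> lc;
  int t;  // snapshot index (1-based), for feature-gradient bookkeeping
};

// logmask: N x N, 0 where attention allowed, -Inf where forbidden
static mat make_logmask(const mat& M) {
  mat lm(size(M), fill::zeros);
  lm.elem(find(M == 0)).fill(-datum::inf);
  return lm;
}

static mat encode_forward(const Params& P, const mat& H0, const mat& logmask,
                          EncodeCache* cache) {
  const int Hh = P.n_heads;
  const uword N = H0.n_rows, D = H0.n_cols;
  const uword dh = D / Hh;
  const double scale = 1.0 / std::sqrt((double)dh);
  mat H = H0;
  for (size_t li = 0; li < P.layers.size(); ++li) {
    const Layer& L = P.layers[li];
    LayerCache LC;
    LC.Hin = H;
    LC.Q = H * L.Wq; LC.K = H * L.Wk; LC.V = H * L.Wv;
    LC.A.set_size(N, N, Hh);
    mat concatO(N, D);
    for (int h = 0; h < Hh; ++h) {
      span cs(h * dh, (h + 1) * dh - 1);
      mat S = LC.Q.cols(cs) * LC.K.cols(cs).t() * scale + logmask;
      // row-wise softmax; exp(-Inf) = 0 keeps masked weights exactly zero
      S.each_col() -= max(S, 1);
      S = exp(S);
      S.each_col() /= sum(S, 1);
      LC.A.slice(h) = S;
      concatO.cols(cs) = S * LC.V.cols(cs);
    }
    mat O = concatO * L.Wo;
    mat H1 = layernorm_forward(LC.Hin + O, L.ln1g, L.ln1b, LC.xhat1, LC.istd1);
    LC.H1 = H1;
    LC.U = H1 * L.W1;
    LC.U.each_row() += L.b1.t();
    mat F = clamp(LC.U, 0.0, datum::inf) * L.W2;
    F.each_row() += L.b2.t();
    H = layernorm_forward(H1 + F, L.ln2g, L.ln2b, LC.xhat2, LC.istd2);
    if (cache) cache->lc.push_back(LC);
    if (!H.is_finite())
      Rcpp::stop("non-finite values in encoder forward pass at layer %d",
                 (int)li + 1);
  }
  return H;
}

// Backward through one encode. dH is the gradient w.r.t. the encoder output.
// Returns gradient w.r.t. H0. When attn_grads is non-null, stores dLoss/dA
// per layer (same layout as the cached A).
static mat encode_backward(const Params& P, const EncodeCache& cache, mat dH,
                           Grads& G, std::vector<cube>* attn_grads) {
  const int Hh = P.n_heads;
  const uword D = dH.n_cols;
  const uword dh = D / Hh;
  const double scale = 1.0 / std::sqrt((double)dh);
  if (attn_grads) attn_grads->resize(P.layers.size());
  for (int li = (int)P.layers.size() - 1; li >= 0; --li) {
    const Layer& L = P.layers[li];
    const LayerCache& LC = cache.lc[li];
    Layer& GL = G.layers[li];
    // LN2
    mat dR2 = layernorm_backward(dH, L.ln2g, LC.xhat2, LC.istd2,
                                 GL.ln2g, GL.ln2b);
    // FFN: F = relu(U) W2 + b2, U = H1 W1 + b1
    mat Urelu = clamp(LC.U, 0.0, datum::inf);
    mat dUrelu = dR2 * L.W2.t();
    GL.W2 += Urelu.t() * dR2;
    GL.b2 += sum(dR2, 0).t();
    mat dU = dUrelu % conv_to<mat>::from(LC.U > 0);
    GL.W1 += LC.H1.t() * dU;
    GL.b1 += sum(dU, 0).t();
    mat dH1 = dR2 + dU * L.W1.t();
    // LN1
    mat dR1 = layernorm_backward(dH1, L.ln1g, LC.xhat1, LC.istd1,
                                 GL.ln1g, GL.ln1b);
    // attention: O = concat(A_h V_h) Wo
    mat concatO(size(dR1));
    for (int h = 0; h < Hh; ++h) {
      span cs(h * dh, (h + 1) * dh - 1);
      concatO.cols(cs) = LC.A.slice(h) * LC.V.cols(cs);
    }
    GL.Wo += concatO.t() * dR1;
    mat dConcat = dR1 * L.Wo.t();
    mat dQ(size(LC.Q), fill::zeros), dK(size(LC.K), fill::zeros),
        dV(size(LC.V), fill::zeros);
    if (attn_grads) (*attn_grads)[li].set_size(LC.A.n_rows, LC.A.n_cols, Hh);
    for (int h = 0; h < Hh; ++h) {
      span cs(h * dh, (h + 1) * dh - 1);
      const mat& A = LC.A.slice(h);
      mat dOh = dConcat.cols(cs);
      mat dA = dOh * LC.V.cols(cs).t();
      if (attn_grads) (*attn_grads)[li].slice(h) = dA;
      dV.cols(cs) += A.t() * dOh;
      // softmax backward (masked entries have A = 0, hence dS = 0 there)
      mat dS = A % dA;
      dS -= A.each_col() % sum(A % dA, 1);
      dQ.cols(cs) += dS * LC.K.cols(cs) * scale;
      dK.cols(cs) += dS.t() * LC.Q.cols(cs) * scale;
    }
    GL.Wq += LC.Hin.t() * dQ;
    GL.Wk += LC.Hin.t() * dK;
    GL.Wv += LC.Hin.t() * dV;
    dH = dR1 + dQ * L.Wq.t() + dK * L.Wk.t() + dV * L.Wv.t();
  }
  return dH;  // gradient w.r.t. H0
}

// ---- projection head ------------------------------------------------------

struct HeadCache { vec z, a1, a2; };

static vec head_forward(const Params& P, const vec& z, HeadCache* hc) {
  vec u1 = P.Wh1.t() * z + P.bh1;
  vec a1 = clamp(u1, 0.0, datum::inf);
  vec u2 = P.Wh2.t() * a1 + P.bh2;
  vec a2 = clamp(u2, 0.0, datum::inf);
  vec g = P.Wh3.t() * a2 + P.bh3;
  if (hc) { hc->z = z; hc->a1 = a1; hc->a2 = a2; }
  return g;
}

static vec head_backward(const Params& P, const HeadCache& hc, const vec& dg,
                         Grads& G) {
  G.Wh3 += hc.a2 * dg.t();
  G.bh3 += dg;
  vec da2 = P.Wh3 * dg;
  vec du2 = da2 % conv_to<vec>::from(hc.a2 > 0);
  G.Wh2 += hc.a1 * du2.t();
  G.bh2 += du2;
  vec da1 = P.Wh2 * du2;
  vec du1 = da1 % conv_to<vec>::from(hc.a1 > 0);
  G.Wh1 += hc.z * du1.t();
  G.bh1 += du1;
  return P.Wh1 * du1;  // dz
}

// ---- feature input --------------------------------------------------------

// Xraw_list: either length T (per-snapshot raw features) or length 1
// (shared). pe: n x d_m positional encodings or 0 x 0 when disabled.
struct FeatureCtx {
  const Rcpp::List& xraw;
  const mat& pe;
  bool shared;
  FeatureCtx(const Rcpp::List& x, const mat& p)
    : xraw(x), pe(p), shared(x.size() == 1) {}
  mat raw(int t) const {  // t is 1-based snapshot index
    return Rcpp::as<mat>(xraw[shared ? 0 : (t - 1)]);
  }
};

static mat build_input(const Params& P, const FeatureCtx& FC, const vec& z_prev,
                       int t) {
  mat Xr = FC.raw(t);
  mat Xf = Xr * P.Wf;
  Xf.each_row() += P.bf.t();
  if (FC.pe.n_rows > 0) Xf += FC.pe;
  mat H0(Xr.n_rows + 1, P.bf.n_elem);
  H0.row(0) = z_prev.t();
  H0.rows(1, Xr.n_rows) = Xf;
  return H0;
}

// dH0 -> gradients for Wf, bf (and returns dz_prev)
static vec input_backward(const Params& P, const FeatureCtx& FC, int t,
                          const mat& dH0, Grads& G) {
  mat dXf = dH0.rows(1, dH0.n_rows - 1);
  G.Wf += FC.raw(t).t() * dXf;
  G.bf += sum(dXf, 0).t();
  return dH0.row(0).t();
}

// ---- window forward/backward ----------------------------------------------

// Encodes snapshots ts[0..m-1] sequentially, master state carried through;
// initial master is P.z0. Returns the master output after each encode.
static std::vector<vec> window_forward(const Params& P, const FeatureCtx& FC,
                                       const Rcpp::List& masks,
                                       const std::vector<int>& ts,
                                       std::vector<EncodeCache>* caches,
                                       std::vector<mat>* logmasks) {
  vec z = P.z0;
  std::vector<vec> zs;
  for (size_t i = 0; i < ts.size(); ++i) {
    int t = ts[i];
    mat lm = make_logmask(Rcpp::as<mat>(masks[t - 1]));
    mat H0 = build_input(P, FC, z, t);
    EncodeCache* cc = nullptr;
    if (caches) { caches->push_back(EncodeCache()); cc = &caches->back();
                  cc->t = t; }
    mat H = encode_forward(P, H0, lm, cc);
    z = H.row(0).t();
    zs.push_back(z);
    if (logmasks) logmasks->push_back(lm);
  }
  return zs;
}

// dzs[i]: direct gradient on the master output of encode i (may be zero).
static void window_backward(const Params& P, const FeatureCtx& FC,
                            const std::vector<EncodeCache>& caches,
                            const std::vector<vec>& dzs, Grads& G) {
  const uword D = P.z0.n_elem;
  vec carry(D, fill::zeros);
  for (int i = (int)caches.size() - 1; i >= 0; --i) {
    vec dz = dzs[i] + carry;
    mat dH(caches[i].lc[0].Hin.n_rows, D, fill::zeros);
    dH.row(0) = dz.t();
    mat dH0 = encode_backward(P, caches[i], dH, G, nullptr);
    carry = input_backward(P, FC, caches[i].t, dH0, G);
  }
  G.z0 += carry;
}

// ---- exported entry points ------------------------------------------------

// One contrastive training step over a batch of anchors. For each anchor t,
// the master state is rolled over the window [t-l+1, t] and one more step to
// t+1 (the positive). InfoNCE: the numerator is exp(g_t . g_{t+1} / tau);
// the denominator has B terms — the positive plus the embeddings of the
// other B-1 sampled time points (the negative pairs (g_t, g_{t_j})).
// Returns the mean loss, accumulated parameter gradients, the embeddings.
// [[Rcpp::export]]
Rcpp::List cpp_train_step(const Rcpp::List& params, const Rcpp::List& xraw_list,
                          const Rcpp::List& masks, const arma::mat& pe,
                          const Rcpp::IntegerVector& anchors, int window_l,
                          int n_heads, double tau, double embed_reg,
                          bool normalize) {
  Params P = params_from_list(params, n_heads);
  FeatureCtx FC(xraw_list, pe);
  const int B = anchors.size();
  const uword d = P.bh3.n_elem;

  std::vector<std::vector<EncodeCache>> caches(B);
  std::vector<HeadCache> hc_anchor(B), hc_pos(B);
  mat Ga(B, d), Gp(B, d);
  for (int a = 0; a < B; ++a) {
    int t = anchors[a];
    std::vector<int> ts;
    for (int u = t - window_l + 1; u <= t + 1; ++u) ts.push_back(u);
    std::vector<vec> zs = window_forward(P, FC, masks, ts, &caches[a], nullptr);
    Ga.row(a) = head_forward(P, zs[zs.size() - 2], &hc_anchor[a]).t();
    Gp.row(a) = head_forward(P, zs[zs.size() - 1], &hc_pos[a]).t();
  }

  // Batch-normalise the 2B embeddings per dimension (centred, total
  // variance 1 so |g| is of order one): removes the scale degree of freedom
  // of the raw dot product, which otherwise lets the loss saturate by norm
  // growth or stall in a collapsed state, and keeps tau = 1 in the soft
  // softmax regime. The similarity itself remains the raw dot product.
  mat Ga_n = Ga, Gp_n = Gp;
  rowvec bn_mu, bn_sd;
  double bn_c = 1.0;
  if (normalize) {
    mat Gall = join_cols(Ga, Gp);
    bn_mu = mean(Gall, 0);
    bn_sd = sqrt(var(Gall, 1, 0) + 1e-8);
    bn_c = std::sqrt((double)d);
    Ga_n = Ga.each_row() - bn_mu; Ga_n.each_row() /= (bn_sd * bn_c);
    Gp_n = Gp.each_row() - bn_mu; Gp_n.each_row() /= (bn_sd * bn_c);
  }

  // batch InfoNCE: the denominator of anchor a runs over the B positive
  // embeddings (its own positive plus those of the other anchors)
  mat S = Ga_n * Gp_n.t() / tau;
  vec rowmax = max(S, 1);
  mat E = exp(S.each_col() - rowmax);
  vec denom = sum(E, 1);
  vec loss_i = -(S.diag() - rowmax - log(denom));
  double loss = mean(loss_i);
  mat Pm = E.each_col() / denom;
  mat dS = (Pm - eye(B, B)) / B;
  mat dGa = dS * Gp_n / tau;
  mat dGp = dS.t() * Ga_n / tau;
  if (normalize) {
    // backward through the batch normalisation over the joint 2B batch
    mat dYn = join_cols(dGa, dGp) / bn_c;       // grad w.r.t. (x - mu)/sd
    mat Yh = join_cols(Ga_n, Gp_n) * bn_c;      // standardised values
    rowvec m1 = mean(dYn, 0);
    rowvec m2 = mean(dYn % Yh, 0);
    mat dX = dYn.each_row() - m1;
    dX -= Yh.each_row() % m2;
    dX.each_row() /= bn_sd;
    dGa = dX.rows(0, B - 1);
    dGp = dX.rows(B, 2 * B - 1);
  }
  if (embed_reg > 0) {
    // mild ridge on embedding magnitudes: keeps dot-product similarities in
    // the soft-softmax regime instead of saturating as |g| grows
    loss += embed_reg * 0.5 * (accu(square(Ga)) + accu(square(Gp))) / B;
    dGa += embed_reg * Ga / B;
    dGp += embed_reg * Gp / B;
  }

  Grads G = zero_grads(P);
  for (int a = 0; a < B; ++a) {
    vec dz_anchor = head_backward(P, hc_anchor[a], dGa.row(a).t(), G);
    vec dz_pos = head_backward(P, hc_pos[a], dGp.row(a).t(), G);
    std::vector<vec> dzs(caches[a].size(), zeros<vec>(P.z0.n_elem));
    dzs[dzs.size() - 2] = dz_anchor;
    dzs[dzs.size() - 1] = dz_pos;
    window_backward(P, FC, caches[a], dzs, G);
  }
  return Rcpp::List::create(
    Rcpp::Named("loss") = loss,
    Rcpp::Named("grads") = grads_to_list(G),
    Rcpp::Named("g_anchor") = Ga,
    Rcpp::Named("g_pos") = Gp);
}

// Embed the full sequence with sliding windows: the embedding of snapshot t
// is the master output after rolling the master state from the learnable
// initial vector over [t - window_l + 1, t] (truncated at the sequence
// start), the same depth used for anchors during training. Returns master
// states Z (T x d_m) and final embeddings G (T x d).
// [[Rcpp::export]]
Rcpp::List cpp_embed_sequence(const Rcpp::List& params,
                              const Rcpp::List& xraw_list,
                              const Rcpp::List& masks, const arma::mat& pe,
                              int window_l, int n_heads) {
  Params P = params_from_list(params, n_heads);
  FeatureCtx FC(xraw_list, pe);
  const int T = masks.size();
  mat Z(T, P.z0.n_elem), Gm(T, P.bh3.n_elem);
  // logmasks are reused across overlapping windows; precompute once
  std::vector<mat> lms(T);
  for (int t = 0; t < T; ++t)
    lms[t] = make_logmask(Rcpp::as<mat>(masks[t]));
  for (int t = 1; t <= T; ++t) {
    vec z = P.z0;
    for (int u = std::max(1, t - window_l + 1); u <= t; ++u) {
      mat H0 = build_input(P, FC, z, u);
      mat H = encode_forward(P, H0, lms[u - 1], nullptr);
      z = H.row(0).t();
    }
    Z.row(t - 1) = z.t();
    Gm.row(t - 1) = head_forward(P, z, nullptr).t();
  }
  return Rcpp::List::create(Rcpp::Named("Z") = Z, Rcpp::Named("G") = Gm);
}

// Encode one snapshot from a given master state; returns the new master
// state, the embedding, per-layer attention cubes, and — when grad_g is
// non-empty — the gradients of (grad_g . g_t) w.r.t. each attention matrix,
// as needed by attention-gradient relevance propagation.
// [[Rcpp::export]]
Rcpp::List cpp_encode_snapshot(const Rcpp::List& params, const arma::vec& z_prev,
                               const Rcpp::List& xraw_list, const arma::mat& mask,
                               const arma::mat& pe, int t, int n_heads,
                               const arma::vec& grad_g) {
  Params P = params_from_list(params, n_heads);
  FeatureCtx FC(xraw_list, pe);
  mat lm = make_logmask(mask);
  mat H0 = build_input(P, FC, z_prev, t);
  EncodeCache cache; cache.t = t;
  mat H = encode_forward(P, H0, lm, &cache);
  vec z = H.row(0).t();
  HeadCache hc;
  vec g = head_forward(P, z, &hc);

  Rcpp::List attn(P.layers.size()), attn_grad(P.layers.size());
  for (size_t li = 0; li < P.layers.size(); ++li)
    attn[li] = cache.lc[li].A;
  if (grad_g.n_elem > 0) {
    Grads G = zero_grads(P);
    vec dz = head_backward(P, hc, grad_g, G);
    mat dH(H0.n_rows, H0.n_cols, fill::zeros);
    dH.row(0) = dz.t();
    std::vector<cube> ag;
    encode_backward(P, cache, dH, G, &ag);
    for (size_t li = 0; li < ag.size(); ++li) attn_grad[li] = ag[li];
  }
  return Rcpp::List::create(
    Rcpp::Named("z") = z, Rcpp::Named("g") = g,
    Rcpp::Named("attention") = attn,
    Rcpp::Named("attention_grad") = attn_grad);
}

// Forward + backward of an arbitrary scalar objective grad on the master
// outputs of a window; used by tests for finite-difference verification.
// dz_list: one d_m gradient vector per encoded snapshot.
// [[Rcpp::export]]
Rcpp::List cpp_window_grads(const Rcpp::List& params, const Rcpp::List& xraw_list,
                            const Rcpp::List& masks, const arma::mat& pe,
                            const Rcpp::IntegerVector& ts, int n_heads,
                            const Rcpp::List& dz_list) {
  Params P = params_from_list(params, n_heads);
  FeatureCtx FC(xraw_list, pe);
  std::vector<int> tv(ts.begin(), ts.end());
  std::vector<EncodeCache> caches;
  std::vector<vec> zs = window_forward(P, FC, masks, tv, &caches, nullptr);
  std::vector<vec> dzs;
  for (int i = 0; i < dz_list.size(); ++i)
    dzs.push_back(Rcpp::as<vec>(dz_list[i]));
  Grads G = zero_grads(P);
  window_backward(P, FC, caches, dzs, G);
  mat Z(zs.size(), P.z0.n_elem);
  for (size_t i = 0; i < zs.size(); ++i) Z.row(i) = zs[i].t();
  return Rcpp::List::create(Rcpp::Named("Z") = Z,
                            Rcpp::Named("grads") = grads_to_list(G));
}
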