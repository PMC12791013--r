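// Transformer-encoder backbone for keypoint imputation.
//
// Tokens are (frame, keypoint) pairs: token i (0-based) maps to frame
// i / K and keypoint i % K, matching the array layout built on the R side.
// Each token carries its D coordinates plus the binary gap-mask bit; the
// shared linear projection of [coords, mask] is summed with lookup-table
// embeddings of the time index, the keypoint identity and the mask bit.
// Post-LN encoder layers (MHSA + feed-forward) follow, then linear heads
// for the mean and (probabilistic models) the raw scale.
// [[Rcpp::depends(RcppArmadillo)]]
#include "nn_common.h"
using namespace arma;

struct TfConfig {
  int L, K, D, dm, nh, nl, dff;
  bool proba;
};

static TfConfig tf_config(const Rcpp::List& cfg) {
  TfConfig c;
  c.L = cfg["L"]; c.K = cfg["K"]; c.D = cfg["D"];
  c.dm = cfg["model_dim"]; c.nh = cfg["n_heads"]; c.nl = cfg["n_layers"];
  c.dff = cfg["dff"]; c.proba = cfg["proba"];
  if (c.dm % c.nh != 0) Rcpp::stop("model_dim must be divisible by n_heads");
  return c;
}

static std::vector<ParamSpec> tf_layout(const TfConfig& c) {
  std::vector<ParamSpec> s;
  int din = c.D + 1;
  s.push_back({"W_in", din, c.dm, "linear", din});
  s.push_back({"b_in", 1, c.dm, "bias", din});
  s.push_back({"E_time", c.L, c.dm, "embed", 0});
  s.push_back({"E_kp", c.K, c.dm, "embed", 0});
  s.push_back({"E_mask", 2, c.dm, "embed", 0});
  for (int l = 0; l < c.nl; ++l) {
    std::string p = "layer" + std::to_string(l + 1) + ".";
    s.push_back({p + "Wq", c.dm, c.dm, "linear", c.dm});
    s.push_back({p + "bq", 1, c.dm, "bias", c.dm});
    s.push_back({p + "Wk", c.dm, c.dm, "linear", c.dm});
    s.push_back({p + "bk", 1, c.dm, "bias", c.dm});
    s.push_back({p + "Wv", c.dm, c.dm, "linear", c.dm});
    s.push_back({p + "bv", 1, c.dm, "bias", c.dm});
    s.push_back({p + "Wo", c.dm, c.dm, "linear", c.dm});
    s.push_back({p + "bo", 1, c.dm, "bias", c.dm});
    s.push_back({p + "ln1_g", 1, c.dm, "ln_g", 0});
    s.push_back({p + "ln1_b", 1, c.dm, "ln_b", 0});
    s.push_back({p + "W1", c.dm, c.dff, "linear", c.dm});
    s.push_back({p + "b1", 1, c.dff, "bias", c.dm});
    s.push_back({p + "W2", c.dff, c.dm, "linear", c.dff});
    s.push_back({p + "b2", 1, c.dm, "bias", c.dff});
    s.push_back({p + "ln2_g", 1, c.dm, "ln_g", 0});
    s.push_back({p + "ln2_b", 1, c.dm, "ln_b", 0});
  }
  s.push_back({"W_mu", c.dm, c.D, "linear", c.dm});
  s.push_back({"b_mu", 1, c.D, "bias", c.dm});
  if (c.proba) {
    s.push_back({"W_sg", c.dm, c.D, "linear", c.dm});
    s.push_back({"b_sg", 1, c.D, "bias", c.dm});
  }
  return s;
}

// [[Rcpp::export]]
Rcpp::DataFrame cpp_tf_layout(Rcpp::List cfg) {
  return layout_to_df(tf_layout(tf_config(cfg)));
}

struct TfLayerParams {
  mat Wq, Wk, Wv, Wo, W1, W2;
  rowvec bq, bk, bv, bo, ln1_g, ln1_b, b1, b2, ln2_g, ln2_b;
};

struct TfParams {
  mat W_in, E_time, E_kp, E_mask, W_mu, W_sg;
  rowvec b_in, b_mu, b_sg;
  std::vector<TfLayerParams> layers;
};

static TfParams tf_unpack(const vec& theta, const TfConfig& c) {
  ParamReader rd(theta);
  TfParams p;
  p.W_in = rd.M(c.D + 1, c.dm); p.b_in = rd.V(c.dm);
  p.E_time = rd.M(c.L, c.dm); p.E_kp = rd.M(c.K, c.dm); p.E_mask = rd.M(2, c.dm);
  for (int l = 0; l < c.nl; ++l) {
    TfLayerParams lp;
    lp.Wq = rd.M(c.dm, c.dm); lp.bq = rd.V(c.dm);
    lp.Wk = rd.M(c.dm, c.dm); lp.bk = rd.V(c.dm);
    lp.Wv = rd.M(c.dm, c.dm); lp.bv = rd.V(c.dm);
    lp.Wo = rd.M(c.dm, c.dm); lp.bo = rd.V(c.dm);
    lp.ln1_g = rd.V(c.dm); lp.ln1_b = rd.V(c.dm);
    lp.W1 = rd.M(c.dm, c.dff); lp.b1 = rd.V(c.dff);
    lp.W2 = rd.M(c.dff, c.dm); lp.b2 = rd.V(c.dm);
    lp.ln2_g = rd.V(c.dm); lp.ln2_b = rd.V(c.dm);
    p.layers.push_back(lp);
  }
  p.W_mu = rd.M(c.dm, c.D); p.b_mu = rd.V(c.D);
  if (c.proba) { p.W_sg = rd.M(c.dm, c.D); p.b_sg = rd.V(c.D); }
  rd.done();
  return p;
}

struct TfLayerGrads {
  mat Wq, Wk, Wv, Wo, W1, W2;
  rowvec bq, bk, bv, bo, ln1_g, ln1_b, b1, b2, ln2_g, ln2_b;
  TfLayerGrads(const TfConfig& c) {
    Wq.zeros(c.dm, c.dm); Wk.zeros(c.dm, c.dm); Wv.zeros(c.dm, c.dm); Wo.zeros(c.dm, c.dm);
    W1.zeros(c.dm, c.dff); W2.zeros(c.dff, c.dm);
    bq.zeros(c.dm); bk.zeros(c.dm); bv.zeros(c.dm); bo.zeros(c.dm);
    ln1_g.zeros(c.dm); ln1_b.zeros(c.dm); b1.zeros(c.dff); b2.zeros(c.dm);
    ln2_g.zeros(c.dm); ln2_b.zeros(c.dm);
  }
};

struct TfGrads {
  mat W_in, E_time, E_kp, E_mask, W_mu, W_sg;
  rowvec b_in, b_mu, b_sg;
  std::vector<TfLayerGrads> layers;
  TfGrads(const TfConfig& c) {
    W_in.zeros(c.D + 1, c.dm); b_in.zeros(c.dm);
    E_time.zeros(c.L, c.dm); E_kp.zeros(c.K, c.dm); E_mask.zeros(2, c.dm);
    W_mu.zeros(c.dm, c.D); b_mu.zeros(c.D);
    if (c.proba) { W_sg.zeros(c.dm, c.D); b_sg.zeros(c.D); }
    for (int l = 0; l < c.nl; ++l) layers.push_back(TfLayerGrads(c));
  }
  vec serialize(const TfConfig& c, size_t n) {
    GradWriter w(n);
    w.M(W_in); w.V(b_in); w.M(E_time); w.M(E_kp); w.M(E_mask);
    for (int l = 0; l < c.nl; ++l) {
      TfLayerGrads& g = layers[l];
      w.M(g.Wq); w.V(g.bq); w.M(g.Wk); w.V(g.bk); w.M(g.Wv); w.V(g.bv);
      w.M(g.Wo); w.V(g.bo); w.V(g.ln1_g); w.V(g.ln1_b);
      w.M(g.W1); w.V(g.b1); w.M(g.W2); w.V(g.b2); w.V(g.ln2_g); w.V(g.ln2_b);
    }
    w.M(W_mu); w.V(b_mu);
    if (c.proba) { w.M(W_sg); w.V(b_sg); }
    return w.g;
  }
};

static mat layernorm_fwd(const mat& X, const rowvec& g, const rowvec& b,
                         mat& xhat, vec& inv_sd) {
  vec mu = mean(X, 1);
  mat Xc = X.each_col() - mu;
  vec v = mean(square(Xc), 1);
  inv_sd = 1.0 / sqrt(v + 1e-5);
  xhat = Xc.each_col() % inv_sd;
  mat Y = xhat.each_row() % g;
  Y.each_row() += b;
  return Y;
}

static mat layernorm_bwd(const mat& dY, const mat& xhat, const vec& inv_sd,
                         const rowvec& g, rowvec& dg, rowvec& db) {
  dg += sum(dY % xhat, 0);
  db += sum(dY, 0);
  mat gdy = dY.each_row() % g;
  vec m1 = mean(gdy, 1);
  vec m2 = mean(gdy % xhat, 1);
  mat dX = gdy;
  dX.each_col() -= m1;
  dX -= xhat.each_col() % m2;
  dX.each_col() %= inv_sd;
  return dX;
}

// Attention scores are held transposed (column j = scores of query j so
// the softmax runs over contiguous columns) and normalised in place.
static void softmax_cols_inplace(mat& St, double scale) {
  int n = St.n_rows;
  for (unsigned int j = 0; j < St.n_cols; ++j) {
    double* col = St.colptr(j);
    double mx = col[0];
    for (int i = 1; i < n; ++i) if (col[i] > mx) mx = col[i];
    double s = 0.0;
    for (int i = 0; i < n; ++i) { col[i] = std::exp(scale * (col[i] - mx)); s += col[i]; }
    double inv = 1.0 / s;
    for (int i = 0; i < n; ++i) col[i] *= inv;
  }
}

struct TfLayerCache {
  mat Hin, Q, Kx, V, Ocat, xhat1, H1, Fpre, Frelu, xhat2, Hout;
  vec invsd1, invsd2;
  cube A; // transposed attention weights per head (A(i,j) = weight of key i for query j)
};

struct TfCache {
  mat H0;               // embedded input
  std::vector<TfLayerCache> layers;
  mat Hfin;             // final encoder output
};

// forward for one sample; X is n_tok x (D+1)
static void tf_forward_one(const mat& X, const TfParams& p, const TfConfig& c,
                           const uvec& tidx, const uvec& kidx, TfCache& cc) {
  int dh = c.dm / c.nh;
  int n = c.L * c.K;
  uvec midx(n);
  for (int i = 0; i < n; ++i) midx[i] = X(i, c.D) != 0.0 ? 1 : 0;
  mat H = X * p.W_in;
  H.each_row() += p.b_in;
  H += p.E_time.rows(tidx) + p.E_kp.rows(kidx) + p.E_mask.rows(midx);
  cc.H0 = H;
  cc.layers.resize(c.nl);
  double scale = 1.0 / std::sqrt((double)dh);
  for (int l = 0; l < c.nl; ++l) {
    const TfLayerParams& lp = p.layers[l];
    TfLayerCache& lc = cc.layers[l];
    lc.Hin = H;
    lc.Q = H * lp.Wq; lc.Q.each_row() += lp.bq;
    lc.Kx = H * lp.Wk; lc.Kx.each_row() += lp.bk;
    lc.V = H * lp.Wv; lc.V.each_row() += lp.bv;
    lc.A.set_size(n, n, c.nh);
    lc.Ocat.set_size(n, c.dm);
    for (int h = 0; h < c.nh; ++h) {
      int c0 = h * dh, c1 = (h + 1) * dh - 1;
      mat& At = lc.A.slice(h);
      At = lc.Kx.cols(c0, c1) * lc.Q.cols(c0, c1).t();
      softmax_cols_inplace(At, scale);
      lc.Ocat.cols(c0, c1) = At.t() * lc.V.cols(c0, c1);
    }
    mat O = lc.Ocat * lp.Wo;
    O.each_row() += lp.bo;
    mat R1 = lc.Hin + O;
    lc.H1 = layernorm_fwd(R1, lp.ln1_g, lp.ln1_b, lc.xhat1, lc.invsd1);
    lc.Fpre = lc.H1 * lp.W1;
    lc.Fpre.each_row() += lp.b1;
    lc.Frelu = clamp(lc.Fpre, 0.0, datum::inf);
    mat F2 = lc.Frelu * lp.W2;
    F2.each_row() += lp.b2;
    mat R2 = lc.H1 + F2;
    lc.Hout = layernorm_fwd(R2, lp.ln2_g, lp.ln2_b, lc.xhat2, lc.invsd2);
    H = lc.Hout;
  }
  cc.Hfin = H;
}

// backward through encoder for one sample given dH at the final output
static void tf_backward_one(mat dH, const mat& X, const TfParams& p, const TfConfig& c,
                            const uvec& tidx, const uvec& kidx, const TfCache& cc,
                            TfGrads& g) {
  int dh = c.dm / c.nh;
  int n = c.L * c.K;
  double scale = 1.0 / std::sqrt((double)dh);
  for (int l = c.nl - 1; l >= 0; --l) {
    const TfLayerParams& lp = p.layers[l];
    const TfLayerCache& lc = cc.layers[l];
    TfLayerGrads& lg = g.layers[l];
    mat dR2 = layernorm_bwd(dH, lc.xhat2, lc.invsd2, lp.ln2_g, lg.ln2_g, lg.ln2_b);
    mat dH1 = dR2;
    lg.W2 += lc.Frelu.t() * dR2;
    lg.b2 += sum(dR2, 0);
    mat dFrelu = dR2 * lp.W2.t();
    mat dFpre = dFrelu % conv_to<mat>::from(lc.Fpre > 0.0);
    lg.W1 += lc.H1.t() * dFpre;
    lg.b1 += sum(dFpre, 0);
    dH1 += dFpre * lp.W1.t();
    mat dR1 = layernorm_bwd(dH1, lc.xhat1, lc.invsd1, lp.ln1_g, lg.ln1_g, lg.ln1_b);
    mat dHin = dR1;
    lg.Wo += lc.Ocat.t() * dR1;
    lg.bo += sum(dR1, 0);
    mat dOcat = dR1 * lp.Wo.t();
    mat dQ(n, c.dm), dK(n, c.dm), dV(n, c.dm);
    mat dAt(n, n);
    for (int h = 0; h < c.nh; ++h) {
      int c0 = h * dh, c1 = (h + 1) * dh - 1;
      const mat& At = lc.A.slice(h);
      mat dOh = dOcat.cols(c0, c1);
      dAt = lc.V.cols(c0, c1) * dOh.t();
      dV.cols(c0, c1) = At * dOh;
      // softmax backward, in place per (contiguous) column
      for (int j = 0; j < n; ++j) {
        const double* a = At.colptr(j);
        double* d = dAt.colptr(j);
        double sdot = 0.0;
        for (int i = 0; i < n; ++i) sdot += d[i] * a[i];
        for (int i = 0; i < n; ++i) d[i] = a[i] * (d[i] - sdot);
      }
      dQ.cols(c0, c1) = scale * (dAt.t() * lc.Kx.cols(c0, c1));
      dK.cols(c0, c1) = scale * (dAt * lc.Q.cols(c0, c1));
    }
    lg.Wq += lc.Hin.t() * dQ; lg.bq += sum(dQ, 0);
    lg.Wk += lc.Hin.t() * dK; lg.bk += sum(dK, 0);
    lg.Wv += lc.Hin.t() * dV; lg.bv += sum(dV, 0);
    dHin += dQ * lp.Wq.t() + dK * lp.Wk.t() + dV * lp.Wv.t();
    dH = dHin;
  }
  // embedding / projection grads
  g.W_in += X.t() * dH;
  g.b_in += sum(dH, 0);
  for (int i = 0; i < n; ++i) {
    g.E_time.row(tidx[i]) += dH.row(i);
    g.E_kp.row(kidx[i]) += dH.row(i);
    int m = X(i, c.D) != 0.0 ? 1 : 0;
    g.E_mask.row(m) += dH.row(i);
  }
}

static void tf_token_index(const TfConfig& c, uvec& tidx, uvec& kidx) {
  int n = c.L * c.K;
  tidx.set_size(n); kidx.set_size(n);
  for (int i = 0; i < n; ++i) { tidx[i] = i / c.K; kidx[i] = i % c.K; }
}

// input: n_tok x (D+1) x B; returns mean/sigma as n_tok x D x B and
// latent (mean over tokens of the final encoder layer) as dm x B
// [[Rcpp::export]]
Rcpp::List cpp_tf_predict(const arma::vec& theta, const arma::cube& input, Rcpp::List cfg) {
  TfConfig c = tf_config(cfg);
  TfParams p = tf_unpack(theta, c);
  int B = input.n_slices, n = c.L * c.K;
  if ((int)input.n_rows != n || (int)input.n_cols != c.D + 1)
    Rcpp::stop("input shape does not match model configuration");
  uvec tidx, kidx;
  tf_token_index(c, tidx, kidx);
  cube mu(n, c.D, B), sg;
  if (c.proba) sg.set_size(n, c.D, B);
  mat latent(c.dm, B);
  TfCache cc; // reused across samples to avoid reallocation
  for (int b = 0; b < B; ++b) {
    tf_forward_one(input.slice(b), p, c, tidx, kidx, cc);
    mat m = cc.Hfin * p.W_mu;
    m.each_row() += p.b_mu;
    mu.slice(b) = m;
    if (c.proba) {
      mat s = cc.Hfin * p.W_sg;
      s.each_row() += p.b_sg;
      sg.slice(b) = softplus(s) + SIGMA_FLOOR;
    }
    latent.col(b) = mean(cc.Hfin, 0).t();
  }
  Rcpp::List out = Rcpp::List::create(Rcpp::Named("mean") = mu,
                                      Rcpp::Named("latent") = latent);
  if (c.proba) out["std"] = sg;
  return out;
}

// loss + gradient over a batch; target n_tok x D x B, cellmask n_tok x B
// (token-level mask; all D coordinates of a masked token count)
// [[Rcpp::export]]
Rcpp::List cpp_tf_grad(const arma::vec& theta, const arma::cube& input,
                       const arma::cube& target, const arma::mat& tokmask,
                       Rcpp::List cfg, std::string loss) {
  TfConfig c = tf_config(cfg);
  TfParams p = tf_unpack(theta, c);
  int B = input.n_slices, n = c.L * c.K;
  uvec tidx, kidx;
  tf_token_index(c, tidx, kidx);
  double ntot = accu(tokmask) * c.D;
  if (ntot <= 0) Rcpp::stop("no masked cells: loss undefined");
  TfGrads g(c);
  double total = 0.0;
  cube mu(n, c.D, B);
  TfCache cc; // reused across samples to avoid reallocation
  for (int b = 0; b < B; ++b) {
    tf_forward_one(input.slice(b), p, c, tidx, kidx, cc);
    mat m = cc.Hfin * p.W_mu;
    m.each_row() += p.b_mu;
    mu.slice(b) = m;
    mat sraw;
    if (c.proba) {
      sraw = cc.Hfin * p.W_sg;
      sraw.each_row() += p.b_sg;
    }
    mat cellmask = repmat(tokmask.col(b), 1, c.D);
    mat dmu, dsraw;
    total += loss_grad_block(m, sraw, target.slice(b), cellmask, loss, ntot, c.proba, dmu, dsraw);
    g.W_mu += cc.Hfin.t() * dmu;
    g.b_mu += sum(dmu, 0);
    mat dH = dmu * p.W_mu.t();
    if (c.proba && loss == "nll") {
      g.W_sg += cc.Hfin.t() * dsraw;
      g.b_sg += sum(dsraw, 0);
      dH += dsraw * p.W_sg.t();
    }
    tf_backward_one(dH, input.slice(b), p, c, tidx, kidx, cc, g);
  }
  return Rcpp::List::create(Rcpp::Named("loss") = total,
                            Rcpp::Named("grad") = g.serialize(c, theta.n_elem),
                            Rcpp::Named("mean") = mu);
}
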