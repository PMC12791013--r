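// Temporal convolutional network backbone: residual blocks of two causal
// dilated 1D convolutions (kernel 3 by default) with ReLU and inverted
// dropout, dilation doubling per block (1, 2, 4, 8). A 1x1 output
// convolution maps hidden channels to K*D means (and raw scales).
// Causality: output at frame t only reads frames <= t (left zero padding).
// [[Rcpp::depends(RcppArmadillo)]]
#include "nn_common.h"
using namespace arma;

struct TcnConfig {
  int L, K, D, C, nb, k;
  double dropout;
  bool proba;
  int C0, Dout;
};

static TcnConfig tcn_config(const Rcpp::List& cfg) {
  TcnConfig c;
  c.L = cfg["L"]; c.K = cfg["K"]; c.D = cfg["D"];
  c.C = cfg["hidden"]; c.nb = cfg["n_blocks"]; c.k = cfg["kernel"];
  c.dropout = cfg["dropout"]; c.proba = cfg["proba"];
  c.C0 = c.K * (c.D + 1);
  c.Dout = c.K * c.D;
  return c;
}

static std::vector<ParamSpec> tcn_layout(const TcnConfig& c) {
  std::vector<ParamSpec> s;
  for (int b = 0; b < c.nb; ++b) {
    int cin = (b == 0) ? c.C0 : c.C;
    std::string p = "block" + std::to_string(b + 1) + ".";
    s.push_back({p + "W1", c.k * cin, c.C, "linear", c.k * cin});
    s.push_back({p + "b1", 1, c.C, "bias", c.k * cin});
    s.push_back({p + "W2", c.k * c.C, c.C, "linear", c.k * c.C});
    s.push_back({p + "b2", 1, c.C, "bias", c.k * c.C});
    if (cin != c.C) s.push_back({p + "Wres", cin, c.C, "linear", cin});
  }
  s.push_back({"W_mu", c.C, c.Dout, "linear", c.C});
  s.push_back({"b_mu", 1, c.Dout, "bias", c.C});
  if (c.proba) {
    s.push_back({"W_sg", c.C, c.Dout, "linear", c.C});
    s.push_back({"b_sg", 1, c.Dout, "bias", c.C});
  }
  return s;
}

// [[Rcpp::export]]
Rcpp::DataFrame cpp_tcn_layout(Rcpp::List cfg) {
  return layout_to_df(tcn_layout(tcn_config(cfg)));
}

struct TcnBlockParams { mat W1, W2, Wres; rowvec b1, b2; bool has_res; };

struct TcnParams {
  std::vector<TcnBlockParams> blocks;
  mat W_mu, W_sg;
  rowvec b_mu, b_sg;
};

static TcnParams tcn_unpack(const vec& theta, const TcnConfig& c) {
  ParamReader rd(theta);
  TcnParams p;
  for (int b = 0; b < c.nb; ++b) {
    int cin = (b == 0) ? c.C0 : c.C;
    TcnBlockParams bp;
    bp.W1 = rd.M(c.k * cin, c.C); bp.b1 = rd.V(c.C);
    bp.W2 = rd.M(c.k * c.C, c.C); bp.b2 = rd.V(c.C);
    bp.has_res = (cin != c.C);
    if (bp.has_res) bp.Wres = rd.M(cin, c.C);
    p.blocks.push_back(bp);
  }
  p.W_mu = rd.M(c.C, c.Dout); p.b_mu = rd.V(c.Dout);
  if (c.proba) { p.W_sg = rd.M(c.C, c.Dout); p.b_sg = rd.V(c.Dout); }
  rd.done();
  return p;
}

// causal dilated conv: in B x Cin x L, W (k*Cin) x Cout with tap j in rows
// [j*Cin, (j+1)*Cin); out[t] = b + sum_j in[t - j*dil] * W_j
static cube causal_conv(const cube& in, const mat& W, const rowvec& b, int k, int dil) {
  int B = in.n_rows, Cin = in.n_cols, L = in.n_slices, Cout = W.n_cols;
  cube out(B, Cout, L);
  for (int t = 0; t < L; ++t) {
    mat o(B, Cout, fill::zeros);
    o.each_row() += b;
    for (int j = 0; j < k; ++j) {
      int src = t - j * dil;
      if (src < 0) continue;
      o += in.slice(src) * W.rows(j * Cin, (j + 1) * Cin - 1);
    }
    out.slice(t) = o;
  }
  return out;
}

static void causal_conv_back(const cube& in, const mat& W, int k, int dil,
                             const cube& dout, mat& dW, rowvec& db, cube& din) {
  int Cin = in.n_cols, L = in.n_slices;
  for (int t = 0; t < L; ++t) {
    const mat& g = dout.slice(t);
    db += sum(g, 0);
    for (int j = 0; j < k; ++j) {
      int src = t - j * dil;
      if (src < 0) continue;
      dW.rows(j * Cin, (j + 1) * Cin - 1) += in.slice(src).t() * g;
      din.slice(src) += g * W.rows(j * Cin, (j + 1) * Cin - 1).t();
    }
  }
}

struct TcnBlockCache {
  cube in, pre1, act1, mask1, pre2, act2, mask2, sum; // act* post-dropout
};

struct TcnCache {
  std::vector<TcnBlockCache> blocks;
  cube out;
};

static cube dropout_mask(int B, int C, int L, double p, std::mt19937& rng) {
  cube m(B, C, L);
  std::bernoulli_distribution bern(1.0 - p);
  double scale = 1.0 / (1.0 - p);
  for (size_t i = 0; i < m.n_elem; ++i) m[i] = bern(rng) ? scale : 0.0;
  return m;
}

static void tcn_forward(const cube& input, const TcnParams& p, const TcnConfig& c,
                        bool training, int seed, TcnCache& cc) {
  std::mt19937 rng(seed);
  bool drop = training && c.dropout > 0.0;
  cube cur = input;
  cc.blocks.resize(c.nb);
  for (int b = 0; b < c.nb; ++b) {
    int dil = 1 << b;
    const TcnBlockParams& bp = p.blocks[b];
    TcnBlockCache& bc = cc.blocks[b];
    bc.in = cur;
    bc.pre1 = causal_conv(cur, bp.W1, bp.b1, c.k, dil);
    bc.act1 = bc.pre1;
    bc.act1.transform([](double v) { return v > 0.0 ? v : 0.0; });
    if (drop) {
      bc.mask1 = dropout_mask(bc.act1.n_rows, bc.act1.n_cols, bc.act1.n_slices, c.dropout, rng);
      bc.act1 %= bc.mask1;
    }
    bc.pre2 = causal_conv(bc.act1, bp.W2, bp.b2, c.k, dil);
    bc.act2 = bc.pre2;
    bc.act2.transform([](double v) { return v > 0.0 ? v : 0.0; });
    if (drop) {
      bc.mask2 = dropout_mask(bc.act2.n_rows, bc.act2.n_cols, bc.act2.n_slices, c.dropout, rng);
      bc.act2 %= bc.mask2;
    }
    cube res;
    if (bp.has_res) {
      res.set_size(cur.n_rows, c.C, c.L);
      for (int t = 0; t < c.L; ++t) res.slice(t) = cur.slice(t) * bp.Wres;
    } else {
      res = cur;
    }
    bc.sum = res + bc.act2;
    cur = bc.sum;
    cur.transform([](double v) { return v > 0.0 ? v : 0.0; });
  }
  cc.out = cur;
}

// [[Rcpp::export]]
Rcpp::List cpp_tcn_predict(const arma::vec& theta, const arma::cube& input, Rcpp::List cfg) {
  TcnConfig c = tcn_config(cfg);
  TcnParams p = tcn_unpack(theta, c);
  if ((int)input.n_cols != c.C0 || (int)input.n_slices != c.L)
    Rcpp::stop("input shape does not match model configuration");
  int B = input.n_rows;
  TcnCache cc;
  tcn_forward(input, p, c, false, 0, cc);
  cube mu(B, c.Dout, c.L), sg;
  if (c.proba) sg.set_size(B, c.Dout, c.L);
  for (int t = 0; t < c.L; ++t) {
    mat m = cc.out.slice(t) * p.W_mu;
    m.each_row() += p.b_mu;
    mu.slice(t) = m;
    if (c.proba) {
      mat s = cc.out.slice(t) * p.W_sg;
      s.each_row() += p.b_sg;
      sg.slice(t) = softplus(s) + SIGMA_FLOOR;
    }
  }
  Rcpp::List out = Rcpp::List::create(Rcpp::Named("mean") = mu);
  if (c.proba) out["std"] = sg;
  return out;
}

// [[Rcpp::export]]
Rcpp::List cpp_tcn_grad(const arma::vec& theta, const arma::cube& input,
                        const arma::cube& target, const arma::cube& kpmask,
                        Rcpp::List cfg, std::string loss, bool training, int seed) {
  TcnConfig c = tcn_config(cfg);
  TcnParams p = tcn_unpack(theta, c);
  int B = input.n_rows;
  TcnCache cc;
  tcn_forward(input, p, c, training, seed, cc);
  double ntot = accu(kpmask) * c.D;
  if (ntot <= 0) Rcpp::stop("no masked cells: loss undefined");

  std::vector<TcnBlockParams> gb;
  for (int b = 0; b < c.nb; ++b) {
    int cin = (b == 0) ? c.C0 : c.C;
    TcnBlockParams g;
    g.W1.zeros(c.k * cin, c.C); g.b1.zeros(c.C);
    g.W2.zeros(c.k * c.C, c.C); g.b2.zeros(c.C);
    g.has_res = (cin != c.C);
    if (g.has_res) g.Wres.zeros(cin, c.C);
    gb.push_back(g);
  }
  mat dWmu(c.C, c.Dout, fill::zeros), dWsg;
  rowvec dbmu(c.Dout, fill::zeros), dbsg;
  if (c.proba) { dWsg.zeros(c.C, c.Dout); dbsg.zeros(c.Dout); }

  double total = 0.0;
  cube mu(B, c.Dout, c.L);
  cube dtop(B, c.C, c.L, fill::zeros);
  for (int t = 0; t < c.L; ++t) {
    mat m = cc.out.slice(t) * p.W_mu;
    m.each_row() += p.b_mu;
    mu.slice(t) = m;
    mat sraw;
    if (c.proba) {
      sraw = cc.out.slice(t) * p.W_sg;
      sraw.each_row() += p.b_sg;
    }
    mat cellmask(B, c.Dout);
    for (int k = 0; k < c.K; ++k)
      for (int d = 0; d < c.D; ++d)
        cellmask.col(k * c.D + d) = kpmask.slice(t).col(k);
    mat dmu, dsraw;
    total += loss_grad_block(m, sraw, target.slice(t), cellmask, loss, ntot, c.proba, dmu, dsraw);
    dWmu += cc.out.slice(t).t() * dmu;
    dbmu += sum(dmu, 0);
    dtop.slice(t) = dmu * p.W_mu.t();
    if (c.proba && loss == "nll") {
      dWsg += cc.out.slice(t).t() * dsraw;
      dbsg += sum(dsraw, 0);
      dtop.slice(t) += dsraw * p.W_sg.t();
    }
  }

  cube dcur = dtop;
  bool drop = training && c.dropout > 0.0;
  for (int b = c.nb - 1; b >= 0; --b) {
    int dil = 1 << b;
    int cin = (b == 0) ? c.C0 : c.C;
    const TcnBlockParams& bp = p.blocks[b];
    const TcnBlockCache& bc = cc.blocks[b];
    // through the post-residual ReLU
    cube dsum = dcur;
    for (size_t i = 0; i < dsum.n_elem; ++i) if (bc.sum[i] <= 0.0) dsum[i] = 0.0;
    // residual path
    cube din(B, cin, c.L, fill::zeros);
    if (bp.has_res) {
      for (int t = 0; t < c.L; ++t) {
        gb[b].Wres += bc.in.slice(t).t() * dsum.slice(t);
        din.slice(t) += dsum.slice(t) * bp.Wres.t();
      }
    } else {
      din += dsum;
    }
    // conv2 path
    cube dact2 = dsum;
    if (drop) dact2 %= bc.mask2;
    for (size_t i = 0; i < dact2.n_elem; ++i) if (bc.pre2[i] <= 0.0) dact2[i] = 0.0;
    cube dact1(B, c.C, c.L, fill::zeros);
    causal_conv_back(bc.act1, bp.W2, c.k, dil, dact2, gb[b].W2, gb[b].b2, dact1);
    if (drop) dact1 %= bc.mask1;
    for (size_t i = 0; i < dact1.n_elem; ++i) if (bc.pre1[i] <= 0.0) dact1[i] = 0.0;
    causal_conv_back(bc.in, bp.W1, c.k, dil, dact1, gb[b].W1, gb[b].b1, din);
    dcur = din;
  }

  GradWriter w(theta.n_elem);
  for (int b = 0; b < c.nb; ++b) {
    w.M(gb[b].W1); w.V(gb[b].b1); w.M(gb[b].W2); w.V(gb[b].b2);
    if (gb[b].has_res) w.M(gb[b].Wres);
  }
  w.M(dWmu); w.V(dbmu);
  if (c.proba) { w.M(dWsg); w.V(dbsg); }
  return Rcpp::List::create(Rcpp::Named("loss") = total,
                            Rcpp::Named("grad") = w.g,
                            Rcpp::Named("mean") = mu);
}
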