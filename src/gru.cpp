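// Bidirectional multi-layer GRU backbone.
//
// Per frame, every keypoint contributes D coordinates plus the binary gap
// mask bit, concatenated into one input vector of length K*(D+1). Layers
// are bidirectional: both directions of layer l read the concatenated
// forward/backward outputs of layer l-1. A linear output layer maps the
// 2*hidden features of the last layer to K*D means (and raw scales for
// probabilistic models). Gate equations follow the common convention
//   r = sigm(W_r x + b_r + U_r h + c_r)
//   z = sigm(W_z x + b_z + U_z h + c_z)
//   n = tanh(W_n x + b_n + r .* (U_n h + c_n))
//   h' = (1 - z) .* n + z .* h
// [[Rcpp::depends(RcppArmadillo)]]
#include "nn_common.h"
using namespace arma;

struct GruConfig {
  int L, K, D, H, nl;
  bool proba;
  int F0, Dout;
};

static GruConfig gru_config(const Rcpp::List& cfg) {
  GruConfig c;
  c.L = cfg["L"]; c.K = cfg["K"]; c.D = cfg["D"];
  c.H = cfg["hidden"]; c.nl = cfg["n_layers"]; c.proba = cfg["proba"];
  c.F0 = c.K * (c.D + 1);
  c.Dout = c.K * c.D;
  return c;
}

static std::vector<ParamSpec> gru_layout(const GruConfig& c) {
  std::vector<ParamSpec> s;
  for (int l = 0; l < c.nl; ++l) {
    int fin = (l == 0) ? c.F0 : 2 * c.H;
    for (int d = 0; d < 2; ++d) {
      std::string p = "layer" + std::to_string(l + 1) + (d == 0 ? ".fwd." : ".bwd.");
      s.push_back({p + "W", 3 * c.H, fin, "linear", c.H});
      s.push_back({p + "U", 3 * c.H, c.H, "linear", c.H});
      s.push_back({p + "bx", 1, 3 * c.H, "bias", c.H});
      s.push_back({p + "bh", 1, 3 * c.H, "bias", c.H});
    }
  }
  s.push_back({"W_out", 2 * c.H, c.Dout, "linear", 2 * c.H});
  s.push_back({"b_out", 1, c.Dout, "bias", 2 * c.H});
  if (c.proba) {
    s.push_back({"W_sg", 2 * c.H, c.Dout, "linear", 2 * c.H});
    s.push_back({"b_sg", 1, c.Dout, "bias", 2 * c.H});
  }
  return s;
}

// [[Rcpp::export]]
Rcpp::DataFrame cpp_gru_layout(Rcpp::List cfg) {
  return layout_to_df(gru_layout(gru_config(cfg)));
}

struct GruCell { mat W, U; rowvec bx, bh; };

struct GruParams {
  std::vector<GruCell> cells; // 2 per layer: fwd, bwd
  mat W_out, W_sg;
  rowvec b_out, b_sg;
};

static GruParams gru_unpack(const vec& theta, const GruConfig& c) {
  ParamReader rd(theta);
  GruParams p;
  for (int l = 0; l < c.nl; ++l) {
    int fin = (l == 0) ? c.F0 : 2 * c.H;
    for (int d = 0; d < 2; ++d) {
      GruCell g;
      g.W = rd.M(3 * c.H, fin);
      g.U = rd.M(3 * c.H, c.H);
      g.bx = rd.V(3 * c.H);
      g.bh = rd.V(3 * c.H);
      p.cells.push_back(g);
    }
  }
  p.W_out = rd.M(2 * c.H, c.Dout);
  p.b_out = rd.V(c.Dout);
  if (c.proba) { p.W_sg = rd.M(2 * c.H, c.Dout); p.b_sg = rd.V(c.Dout); }
  rd.done();
  return p;
}

// per-direction cache: gate activations and previous hidden states per step
struct DirCache {
  cube r, z, n, hn, hprev; // each B x H x L, indexed by time step t
};

struct GruCache {
  std::vector<cube> layer_in;   // input to each layer, B x Fin x L
  std::vector<DirCache> dirs;   // 2 per layer
  cube out;                     // final layer output B x 2H x L
};

static void gru_run_dir(const cube& in, const GruCell& cell, const GruConfig& c,
                        bool backward_dir, DirCache& dc, cube& out, int col0) {
  int B = in.n_slices > 0 ? in.slice(0).n_rows : 0;
  (void)B;
  int Bn = in.n_rows;
  int H = c.H;
  dc.r.set_size(Bn, H, c.L); dc.z.set_size(Bn, H, c.L);
  dc.n.set_size(Bn, H, c.L); dc.hn.set_size(Bn, H, c.L);
  dc.hprev.set_size(Bn, H, c.L);
  mat h(Bn, H, fill::zeros);
  for (int s = 0; s < c.L; ++s) {
    int t = backward_dir ? (c.L - 1 - s) : s;
    mat x = in.slice(t);
    mat px = x * cell.W.t();
    px.each_row() += cell.bx;
    mat ph = h * cell.U.t();
    ph.each_row() += cell.bh;
    mat r = sigmoid(px.cols(0, H - 1) + ph.cols(0, H - 1));
    mat z = sigmoid(px.cols(H, 2 * H - 1) + ph.cols(H, 2 * H - 1));
    mat hn = ph.cols(2 * H, 3 * H - 1);
    mat n = tanh(px.cols(2 * H, 3 * H - 1) + r % hn);
    dc.r.slice(t) = r; dc.z.slice(t) = z; dc.n.slice(t) = n;
    dc.hn.slice(t) = hn; dc.hprev.slice(t) = h;
    h = (1.0 - z) % n + z % h;
    out.slice(t).cols(col0, col0 + H - 1) = h;
  }
}

static void gru_forward(const cube& input, const GruParams& p, const GruConfig& c,
                        GruCache& cc) {
  int B = input.n_rows;
  cube cur = input;
  cc.layer_in.resize(c.nl);
  cc.dirs.resize(2 * c.nl);
  for (int l = 0; l < c.nl; ++l) {
    cc.layer_in[l] = cur;
    cube out(B, 2 * c.H, c.L, fill::zeros);
    gru_run_dir(cur, p.cells[2 * l], c, false, cc.dirs[2 * l], out, 0);
    gru_run_dir(cur, p.cells[2 * l + 1], c, true, cc.dirs[2 * l + 1], out, c.H);
    cur = out;
  }
  cc.out = cur;
}

// backward through one direction; dout is B x H x L gradient at this
// direction's hidden outputs; adds input gradients into din
static void gru_back_dir(const cube& in, const GruCell& cell, const GruConfig& c,
                         bool backward_dir, const DirCache& dc, const cube& dout,
                         mat& dW, mat& dU, rowvec& dbx, rowvec& dbh, cube& din) {
  int Bn = in.n_rows;
  int H = c.H;
  mat carry(Bn, H, fill::zeros);
  for (int s = c.L - 1; s >= 0; --s) {
    int t = backward_dir ? (c.L - 1 - s) : s;
    mat dh = dout.slice(t) + carry;
    const mat& r = dc.r.slice(t);
    const mat& z = dc.z.slice(t);
    const mat& n = dc.n.slice(t);
    const mat& hn = dc.hn.slice(t);
    const mat& hprev = dc.hprev.slice(t);
    mat dz = dh % (hprev - n) % z % (1.0 - z);
    mat dn = dh % (1.0 - z) % (1.0 - square(n));
    mat dr = dn % hn % r % (1.0 - r);
    mat dpx(Bn, 3 * H), dph(Bn, 3 * H);
    dpx.cols(0, H - 1) = dr;           dph.cols(0, H - 1) = dr;
    dpx.cols(H, 2 * H - 1) = dz;       dph.cols(H, 2 * H - 1) = dz;
    dpx.cols(2 * H, 3 * H - 1) = dn;   dph.cols(2 * H, 3 * H - 1) = dn % r;
    mat x = in.slice(t);
    dW += dpx.t() * x;
    dU += dph.t() * hprev;
    dbx += sum(dpx, 0);
    dbh += sum(dph, 0);
    din.slice(t) += dpx * cell.W;
    carry = dh % z + dph * cell.U;
  }
}

// input: B x K*(D+1) x L; mean/std: B x K*D x L; latent: 2H x B
// [[Rcpp::export]]
Rcpp::List cpp_gru_predict(const arma::vec& theta, const arma::cube& input, Rcpp::List cfg) {
  GruConfig c = gru_config(cfg);
  GruParams p = gru_unpack(theta, c);
  if ((int)input.n_cols != c.F0 || (int)input.n_slices != c.L)
    Rcpp::stop("input shape does not match model configuration");
  int B = input.n_rows;
  GruCache cc;
  gru_forward(input, p, c, cc);
  cube mu(B, c.Dout, c.L), sg;
  if (c.proba) sg.set_size(B, c.Dout, c.L);
  mat latent(2 * c.H, B, fill::zeros);
  for (int t = 0; t < c.L; ++t) {
    mat m = cc.out.slice(t) * p.W_out;
    m.each_row() += p.b_out;
    mu.slice(t) = m;
    if (c.proba) {
      mat s = cc.out.slice(t) * p.W_sg;
      s.each_row() += p.b_sg;
      sg.slice(t) = softplus(s) + SIGMA_FLOOR;
    }
    latent += cc.out.slice(t).t();
  }
  latent /= (double)c.L;
  Rcpp::List out = Rcpp::List::create(Rcpp::Named("mean") = mu,
                                      Rcpp::Named("latent") = latent);
  if (c.proba) out["std"] = sg;
  return out;
}

// target: B x K*D x L; kpmask: B x K x L (1 = masked keypoint-frame)
// [[Rcpp::export]]
Rcpp::List cpp_gru_grad(const arma::vec& theta, const arma::cube& input,
                        const arma::cube& target, const arma::cube& kpmask,
                        Rcpp::List cfg, std::string loss) {
  GruConfig c = gru_config(cfg);
  GruParams p = gru_unpack(theta, c);
  int B = input.n_rows;
  GruCache cc;
  gru_forward(input, p, c, cc);
  double ntot = accu(kpmask) * c.D;
  if (ntot <= 0) Rcpp::stop("no masked cells: loss undefined");

  // gradient holders mirroring layout order
  std::vector<mat> dW(2 * c.nl), dU(2 * c.nl);
  std::vector<rowvec> dbx(2 * c.nl), dbh(2 * c.nl);
  for (int l = 0; l < c.nl; ++l) {
    int fin = (l == 0) ? c.F0 : 2 * c.H;
    for (int d = 0; d < 2; ++d) {
      dW[2 * l + d].zeros(3 * c.H, fin);
      dU[2 * l + d].zeros(3 * c.H, c.H);
      dbx[2 * l + d].zeros(3 * c.H);
      dbh[2 * l + d].zeros(3 * c.H);
    }
  }
  mat dWout(2 * c.H, c.Dout, fill::zeros), dWsg;
  rowvec dbout(c.Dout, fill::zeros), dbsg;
  if (c.proba) { dWsg.zeros(2 * c.H, c.Dout); dbsg.zeros(c.Dout); }

  double total = 0.0;
  cube mu(B, c.Dout, c.L);
  cube dtop(B, 2 * c.H, c.L, fill::zeros);
  for (int t = 0; t < c.L; ++t) {
    mat m = cc.out.slice(t) * p.W_out;
    m.each_row() += p.b_out;
    mu.slice(t) = m;
    mat sraw;
    if (c.proba) {
      sraw = cc.out.slice(t) * p.W_sg;
      sraw.each_row() += p.b_sg;
    }
    // expand keypoint mask to coordinate cells (columns ordered k-major: D per keypoint)
    mat cellmask(B, c.Dout);
    for (int k = 0; k < c.K; ++k)
      for (int d = 0; d < c.D; ++d)
        cellmask.col(k * c.D + d) = kpmask.slice(t).col(k);
    mat dmu, dsraw;
    total += loss_grad_block(m, sraw, target.slice(t), cellmask, loss, ntot, c.proba, dmu, dsraw);
    dWout += cc.out.slice(t).t() * dmu;
    dbout += sum(dmu, 0);
    dtop.slice(t) = dmu * p.W_out.t();
    if (c.proba && loss == "nll") {
      dWsg += cc.out.slice(t).t() * dsraw;
      dbsg += sum(dsraw, 0);
      dtop.slice(t) += dsraw * p.W_sg.t();
    }
  }

  cube dcur = dtop;
  for (int l = c.nl - 1; l >= 0; --l) {
    int fin = (l == 0) ? c.F0 : 2 * c.H;
    cube din(B, fin, c.L, fill::zeros);
    cube dfwd(B, c.H, c.L), dbwd(B, c.H, c.L);
    for (int t = 0; t < c.L; ++t) {
      dfwd.slice(t) = dcur.slice(t).cols(0, c.H - 1);
      dbwd.slice(t) = dcur.slice(t).cols(c.H, 2 * c.H - 1);
    }
    gru_back_dir(cc.layer_in[l], p.cells[2 * l], c, false, cc.dirs[2 * l], dfwd,
                 dW[2 * l], dU[2 * l], dbx[2 * l], dbh[2 * l], din);
    gru_back_dir(cc.layer_in[l], p.cells[2 * l + 1], c, true, cc.dirs[2 * l + 1], dbwd,
                 dW[2 * l + 1], dU[2 * l + 1], dbx[2 * l + 1], dbh[2 * l + 1], din);
    dcur = din;
  }

  GradWriter w(theta.n_elem);
  for (int l = 0; l < c.nl; ++l)
    for (int d = 0; d < 2; ++d) {
      w.M(dW[2 * l + d]); w.M(dU[2 * l + d]);
      w.V(dbx[2 * l + d]); w.V(dbh[2 * l + d]);
    }
  w.M(dWout); w.V(dbout);
  if (c.proba) { w.M(dWsg); w.V(dbsg); }
  return Rcpp::List::create(Rcpp::Named("loss") = total,
                            Rcpp::Named("grad") = w.g,
                            Rcpp::Named("mean") = mu);
}
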