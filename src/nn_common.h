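// Shared helpers for the native sequence-model backbones.
// Parameters live in one flat vector; each backbone declares a layout
// (ordered list of blocks) used both for initialisation on the R side and
// for sequential unpacking here. Gradients are accumulated in parallel
// matrices and re-serialised in the same order.
#ifndef SKELIMPUTE_NN_COMMON_H
#define SKELIMPUTE_NN_COMMON_H

#include <RcppArmadillo.h>
#include <random>

struct ParamSpec {
  std::string name;
  int r, c;        // matrix dims (vectors as 1 x c)
  std::string kind; // linear | bias | embed | ln_g | ln_b
  int fan;          // fan-in used for uniform init of linear/bias blocks
};

inline Rcpp::DataFrame layout_to_df(const std::vector<ParamSpec>& specs) {
  int m = specs.size();
  Rcpp::CharacterVector name(m), kind(m);
  Rcpp::IntegerVector r(m), c(m), fan(m);
  for (int i = 0; i < m; ++i) {
    name[i] = specs[i].name; r[i] = specs[i].r; c[i] = specs[i].c;
    kind[i] = specs[i].kind; fan[i] = specs[i].fan;
  }
  return Rcpp::DataFrame::create(Rcpp::Named("name") = name,
                                 Rcpp::Named("rows") = r,
                                 Rcpp::Named("cols") = c,
                                 Rcpp::Named("kind") = kind,
                                 Rcpp::Named("fan") = fan);
}

// sequential reader over the flat parameter vector (copies into arma mats)
struct ParamReader {
  const arma::vec& th;
  size_t pos;
  explicit ParamReader(const arma::vec& t) : th(t), pos(0) {}
  arma::mat M(int r, int c) {
    arma::mat m(th.memptr() + pos, r, c);
    pos += (size_t)r * c;
    return m;
  }
  arma::rowvec V(int c) {
    arma::rowvec v(th.memptr() + pos, c);
    pos += (size_t)c;
    return v;
  }
  void done() const {
    if (pos != th.n_elem) Rcpp::stop("parameter vector length does not match layout");
  }
};

// sequential writer serialising gradient blocks back into a flat vector
struct GradWriter {
  arma::vec g;
  size_t pos;
  explicit GradWriter(size_t n) : g(n, arma::fill::zeros), pos(0) {}
  void M(const arma::mat& m) {
    std::copy(m.memptr(), m.memptr() + m.n_elem, g.memptr() + pos);
    pos += m.n_elem;
  }
  void V(const arma::rowvec& v) {
    std::copy(v.memptr(), v.memptr() + v.n_elem, g.memptr() + pos);
    pos += v.n_elem;
  }
};

inline arma::mat softplus(const arma::mat& x) {
  // numerically stable log(1 + exp(x))
  return arma::log1p(arma::exp(-arma::abs(x))) + arma::max(x, arma::zeros<arma::mat>(x.n_rows, x.n_cols));
}

inline arma::mat sigmoid(const arma::mat& x) {
  return 1.0 / (1.0 + arma::exp(-x));
}

const double SIGMA_FLOOR = 1e-4;

// Loss and its gradients w.r.t. mean and raw-scale outputs, restricted to
// masked cells. `cellmask` is 0/1 with the same shape as mu. Contributions
// are normalised by `ntot`, the total masked-cell count over the whole batch.
inline double loss_grad_block(const arma::mat& mu, const arma::mat& sraw,
                              const arma::mat& target, const arma::mat& cellmask,
                              const std::string& loss, double ntot, bool proba,
                              arma::mat& dmu, arma::mat& dsraw) {
  arma::mat r = mu - target;
  double out = 0.0;
  if (loss == "l1") {
    out = arma::accu(arma::abs(r) % cellmask) / ntot;
    dmu = arma::sign(r) % cellmask / ntot;
    if (proba) dsraw.zeros(mu.n_rows, mu.n_cols);
  } else { // gaussian nll
    if (!proba) Rcpp::stop("nll loss requires a probabilistic head");
    arma::mat sg = softplus(sraw) + SIGMA_FLOOR;
    arma::mat s2 = arma::square(sg);
    out = arma::accu((0.5 * std::log(2.0 * M_PI) + arma::log(sg) + arma::square(r) / (2.0 * s2)) % cellmask) / ntot;
    dmu = (r / s2) % cellmask / ntot;
    arma::mat dsg = (1.0 / sg - arma::square(r) / (s2 % sg)) % cellmask / ntot;
    dsraw = dsg % sigmoid(sraw);
  }
  return out;
}

#endif
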