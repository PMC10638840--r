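// Core numerics for the continuous-time Markov engine: matrix exponential
// of t*Q (scaling-and-squaring via Armadillo) and the interval-censored
// panel log-likelihood, which is the hot loop of maximum-likelihood fitting.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// [[Rcpp::export]]
arma::mat expm_rate_cpp(const arma::mat& Q, double t) {
  return arma::expmat(Q * t);
}

// Panel log-likelihood over consecutive-visit intervals.
// Qs: m x m x n_subject cube of per-subject rate matrices.
// from, to: 1-based state indices per interval; dt: interval length (years);
// subj: 1-based subject index per interval.
// Probabilities are floored at 1e-300 before log unless the entry is a
// structural zero of exp(dt*Q) (identically zero transition probability),
// in which case -Inf is returned so the caller can flag the conflict.
// [[Rcpp::export]]
double panel_loglik_cpp(const arma::cube& Qs,
                        const arma::ivec& from,
                        const arma::ivec& to,
                        const arma::vec& dt,
                        const arma::ivec& subj) {
  const arma::uword n = from.n_elem;
  double ll = 0.0;
  arma::mat P;
  arma::uword last_subj = 0;
  double last_dt = -1.0;
  bool have_P = false;
  for (arma::uword i = 0; i < n; ++i) {
    arma::uword s = (arma::uword)(subj[i] - 1);
    double d = dt[i];
    if (!have_P || s != last_subj || d != last_dt) {
      P = arma::expmat(Qs.slice(s) * d);
      last_subj = s; last_dt = d; have_P = true;
    }
    double p = P((arma::uword)(from[i] - 1), (arma::uword)(to[i] - 1));
    if (p <= 0.0) {
      // distinguish round-off from a structural zero: any exit path at all?
      if (p == 0.0) return -arma::datum::inf;
      p = 1e-300;
    }
    if (p < 1e-300) p = 1e-300;
    ll += std::log(p);
  }
  return ll;
}
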