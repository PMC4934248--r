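// Inner recursions for Gaussian-mixture-emission HMMs.
// Observations are T x M (rows = time); state/mixture parameter cubes are
// (S, K, M). All recursions run in log space (log-sum-exp per step), so
// sequences arbitrarily far from the model still yield finite
// log-likelihoods and posteriors.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline double lse(const rowvec& x) {
  double m = x.max();
  if (!std::isfinite(m)) return m;
  return m + std::log(accu(exp(x - m)));
}

// log component densities: cube (T, S, K); also fills logB (T x S) with the
// per-state mixture log density.
static cube log_components(const mat& Y, const mat& w, const cube& mu,
                           const cube& sig2, mat& logB) {
  const uword T = Y.n_rows, M = Y.n_cols, S = w.n_rows, K = w.n_cols;
  cube lc(T, S, K);
  logB.set_size(T, S);
  for (uword s = 0; s < S; ++s) {
    for (uword k = 0; k < K; ++k) {
      rowvec m(M), v(M);
      for (uword d = 0; d < M; ++d) { m(d) = mu(s, k, d); v(d) = sig2(s, k, d); }
      double lognorm = -0.5 * (M * std::log(2.0 * datum::pi) + accu(log(v)));
      mat Z = Y.each_row() - m;
      Z = square(Z);
      Z.each_row() /= v;
      lc.slice(k).col(s) = -0.5 * sum(Z, 1) + lognorm
        + std::log(std::max(w(s, k), 1e-300));
    }
  }
  for (uword t = 0; t < T; ++t) {
    for (uword s = 0; s < S; ++s) {
      double mx = -datum::inf;
      for (uword k = 0; k < K; ++k) mx = std::max(mx, lc(t, s, k));
      double acc = 0.0;
      for (uword k = 0; k < K; ++k) acc += std::exp(lc(t, s, k) - mx);
      logB(t, s) = mx + std::log(acc);
    }
  }
  return lc;
}

// log-space forward pass; returns total log-likelihood and fills lalpha.
static double forward_log(const mat& logB, const vec& logpi,
                          const mat& logA, mat& lalpha) {
  const uword T = logB.n_rows, S = logB.n_cols;
  lalpha.set_size(T, S);
  lalpha.row(0) = logpi.t() + logB.row(0);
  for (uword t = 1; t < T; ++t) {
    for (uword s = 0; s < S; ++s) {
      rowvec prev = lalpha.row(t - 1) + logA.col(s).t();
      lalpha(t, s) = lse(prev) + logB(t, s);
    }
  }
  return lse(lalpha.row(T - 1));
}

// [[Rcpp::export]]
double cpp_hmm_loglik(const arma::mat& Y, const arma::vec& pi,
                      const arma::mat& A, const arma::mat& w,
                      const arma::cube& mu, const arma::cube& sig2) {
  mat logB;
  log_components(Y, w, mu, sig2, logB);
  mat lalpha;
  return forward_log(logB, log(clamp(pi, 1e-300, datum::inf)),
                     log(clamp(A, 1e-300, datum::inf)), lalpha);
}

// log-likelihood of one model against a list of sequences (each T_i x M);
// avoids per-pair call overhead when filling the N x N likelihood matrix.
// [[Rcpp::export]]
arma::vec cpp_hmm_loglik_many(const Rcpp::List& Ys, const arma::vec& pi,
                              const arma::mat& A, const arma::mat& w,
                              const arma::cube& mu, const arma::cube& sig2) {
  const int n = Ys.size();
  vec out(n);
  vec logpi = log(clamp(pi, 1e-300, datum::inf));
  mat logA = log(clamp(A, 1e-300, datum::inf));
  for (int i = 0; i < n; ++i) {
    mat Y = Rcpp::as<mat>(Ys[i]);
    mat logB, lalpha;
    log_components(Y, w, mu, sig2, logB);
    out(i) = forward_log(logB, logpi, logA, lalpha);
  }
  return out;
}

// One E-step for one sequence: returns the sufficient statistics the M-step
// needs, already summed over time.
// [[Rcpp::export]]
Rcpp::List cpp_hmm_estep(const arma::mat& Y, const arma::vec& pi,
                         const arma::mat& A, const arma::mat& w,
                         const arma::cube& mu, const arma::cube& sig2) {
  const uword T = Y.n_rows, M = Y.n_cols, S = w.n_rows, K = w.n_cols;
  mat logB;
  cube lc = log_components(Y, w, mu, sig2, logB);
  vec logpi = log(clamp(pi, 1e-300, datum::inf));
  mat logA = log(clamp(A, 1e-300, datum::inf));
  mat lalpha;
  double ll = forward_log(logB, logpi, logA, lalpha);

  // log-space backward pass
  mat lbeta(T, S, fill::zeros);
  for (uword t = T - 1; t-- > 0;) {
    rowvec nxt = lbeta.row(t + 1) + logB.row(t + 1);
    for (uword s = 0; s < S; ++s)
      lbeta(t, s) = lse(nxt + logA.row(s));
  }

  mat gamma = exp(lalpha + lbeta - ll);
  for (uword t = 0; t < T; ++t) {
    double rs = accu(gamma.row(t));
    if (rs > 0) gamma.row(t) /= rs;
  }

  mat xi(S, S, fill::zeros);
  for (uword t = 0; t + 1 < T; ++t) {
    mat x(S, S);
    for (uword i = 0; i < S; ++i)
      for (uword j = 0; j < S; ++j)
        x(i, j) = lalpha(t, i) + logA(i, j) + logB(t + 1, j)
          + lbeta(t + 1, j) - ll;
    x = exp(x - x.max());
    double xs = accu(x);
    if (xs > 0) xi += x / xs;
  }

  // mixture responsibilities and their moment sums
  mat nk(S, K, fill::zeros);
  cube sum_y(S, K, M, fill::zeros), sum_y2(S, K, M, fill::zeros);
  for (uword s = 0; s < S; ++s) {
    for (uword k = 0; k < K; ++k) {
      vec r = gamma.col(s) % exp(lc.slice(k).col(s) - logB.col(s));
      r.replace(datum::nan, 0.0);
      nk(s, k) = accu(r);
      for (uword d = 0; d < M; ++d) {
        sum_y(s, k, d) = dot(r, Y.col(d));
        sum_y2(s, k, d) = dot(r, square(Y.col(d)));
      }
    }
  }

  return Rcpp::List::create(
    Rcpp::Named("loglik") = ll,
    Rcpp::Named("gamma1") = gamma.row(0).t(),
    Rcpp::Named("xi") = xi,
    Rcpp::Named("nk") = nk,
    Rcpp::Named("sum_y") = sum_y,
    Rcpp::Named("sum_y2") = sum_y2);
}
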