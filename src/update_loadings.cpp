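// Per-unit Newton ascent on the expected Poisson log likelihood for the
// loading matrix and baselines (PLDS M-step), using the log-normal moment
// identity E[exp(c'x)] = exp(c'mu + c'Sigma c / 2) under the Gaussian
// posterior. Posterior covariances enter only through the linear maps
// S_t c and the quadratic forms c'S_t c, so they are flattened once into
// Sflat (p^2 x T) and Srows (T p x p) and every evaluation is a single
// BLAS call. Mirrors update_loadings_r in R/plds-em.R.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export]]
Rcpp::List update_loadings_cpp(const arma::mat& Y, const arma::mat& Mu,
                               const arma::cube& Sig, arma::mat C,
                               arma::vec d, int n_iter) {
  const uword n = Y.n_rows;
  const uword T = Y.n_cols;
  const uword p = Mu.n_rows;

  mat Sflat(p * p, T);   // column t = vec(S_t)
  mat Srows(T * p, p);   // rows t*p..t*p+p-1 = S_t
  for (uword t = 0; t < T; ++t) {
    Sflat.col(t) = vectorise(Sig.slice(t));
    Srows.rows(t * p, t * p + p - 1) = Sig.slice(t);
  }

  auto expected_ll = [&](const vec& c, double d0, const rowvec& yu) {
    vec quad = Sflat.t() * vectorise(c * c.t());
    vec eta = Mu.t() * c + d0;
    vec lam = exp(clamp(eta + 0.5 * quad, -datum::inf, 30.0));
    return dot(yu.t(), eta) - accu(lam);
  };

  for (uword u = 0; u < n; ++u) {
    vec c = C.row(u).t();
    double d0 = d(u);
    rowvec yu = Y.row(u);
    vec y_mu = Mu * yu.t();
    double y_sum = accu(yu);
    double f_cur = expected_ll(c, d0, yu);
    for (int it = 0; it < n_iter; ++it) {
      vec quad = Sflat.t() * vectorise(c * c.t());
      mat Sc = reshape(Srows * c, p, T);
      vec eta = Mu.t() * c + d0 + 0.5 * quad;
      vec rho = exp(clamp(eta, -datum::inf, 30.0));
      mat m_eff = Mu + Sc;
      vec gc = y_mu - m_eff * rho;
      double gd = y_sum - accu(rho);
      if (std::max(abs(gc).max(), std::abs(gd)) < 1e-8) break;
      mat W = m_eff;
      W.each_row() %= rho.t();
      mat Hcc = W * m_eff.t() + reshape(Sflat * rho, p, p);
      vec Hcd = m_eff * rho;
      mat H(p + 1, p + 1);
      H.submat(0, 0, p - 1, p - 1) = Hcc;
      H.submat(0, p, p - 1, p) = Hcd;
      H.submat(p, 0, p, p - 1) = Hcd.t();
      H(p, p) = accu(rho);
      vec g(p + 1);
      g.subvec(0, p - 1) = gc;
      g(p) = gd;
      vec step;
      bool ok = solve(step, H + eye(p + 1, p + 1) * 1e-9, g);
      if (!ok) step = g / (H.diag().max() + 1.0);
      double alpha = 1.0, f_new = f_cur;
      vec c_new = c;
      double d_new = d0;
      while (true) {
        c_new = c + alpha * step.subvec(0, p - 1);
        d_new = d0 + alpha * step(p);
        f_new = expected_ll(c_new, d_new, yu);
        if (f_new >= f_cur || alpha < 1e-6) break;
        alpha *= 0.5;
      }
      if (alpha >= 1e-6 && f_new >= f_cur) {
        c = c_new; d0 = d_new; f_cur = f_new;
      } else break;
    }
    C.row(u) = c.t();
    d(u) = d0;
  }
  return Rcpp::List::create(Rcpp::Named("C") = C, Rcpp::Named("d") = d);
}
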