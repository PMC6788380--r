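// Laplace E-step for the Poisson linear dynamical system: Newton's method on
// the log joint of one latent trajectory, with the block-tridiagonal Hessian
// factorised by forward Schur complements (O(T p^3) per iteration). Mirrors
// the pure-R reference implementation in R/plds-estep.R; agreement between the
// two routes is asserted in the test-suite.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double ETA_CAP = 30.0; // exp overflow guard on the linear predictor

static double neg_logjoint(const mat& X, const mat& Y, const mat& A,
                           const mat& Q0i, const mat& Qi, const mat& C,
                           const vec& d, const vec& x0, double const_term) {
  const uword T = X.n_cols;
  vec v1 = X.col(0) - x0;
  double f = 0.5 * dot(v1, Q0i * v1);
  for (uword t = 1; t < T; ++t) {
    vec dx = X.col(t) - A * X.col(t - 1);
    f += 0.5 * dot(dx, Qi * dx);
  }
  mat eta = C * X;
  eta.each_col() += d;
  mat eta_c = clamp(eta, -datum::inf, ETA_CAP);
  f += accu(exp(eta_c)) - accu(Y % eta);
  return f + const_term;
}

// [[Rcpp::export]]
Rcpp::List plds_estep_cpp(const arma::mat& Y, const arma::mat& A,
                          const arma::mat& Q, const arma::mat& C,
                          const arma::vec& d, const arma::vec& x0,
                          const arma::mat& Q0, const arma::mat& Xinit,
                          int max_iter, double grad_tol, bool want_cov) {
  const uword T = Y.n_cols;
  const uword p = A.n_rows;

  mat Qi = inv_sympd(symmatu(Q));
  mat Q0i = inv_sympd(symmatu(Q0));
  mat AQi = A.t() * Qi;   // A' Q^{-1}
  mat AQiA = AQi * A;     // A' Q^{-1} A
  mat U = -AQi;           // constant (t, t+1) Hessian block

  double ldQ, ldQ0, sign;
  log_det(ldQ, sign, Q);
  log_det(ldQ0, sign, Q0);
  double const_term = 0.5 * (ldQ0 + p * std::log(2.0 * datum::pi)) +
                      (double)(T - 1) * 0.5 * (ldQ + p * std::log(2.0 * datum::pi));
  // sum lgamma(y + 1)
  for (uword i = 0; i < Y.n_elem; ++i) const_term += std::lgamma(Y(i) + 1.0);

  mat X = Xinit;
  double f = neg_logjoint(X, Y, A, Q0i, Qi, C, d, x0, const_term);

  cube Phi(p, p, T);
  mat G(p, T), Cvec(p, T), Z(p, T);
  bool converged = false;
  double gnorm = datum::inf;
  int iter = 0;

  // storage for diagonal Hessian blocks
  cube D(p, p, T);

  auto fill_grad_hess = [&](const mat& Xc) {
    mat eta = C * Xc;
    eta.each_col() += d;
    mat lam = exp(clamp(eta, -datum::inf, ETA_CAP));
    mat gobs = C.t() * (lam - Y);
    for (uword t = 0; t < T; ++t) {
      vec gp;
      if (t == 0) gp = Q0i * (Xc.col(0) - x0);
      else gp = Qi * (Xc.col(t) - A * Xc.col(t - 1));
      if (t + 1 < T) gp -= AQi * (Xc.col(t + 1) - A * Xc.col(t));
      G.col(t) = gp + gobs.col(t);
      mat Dp = (t == 0) ? Q0i : Qi;
      if (t + 1 < T) Dp += AQiA;
      // C' diag(lam_t) C
      mat CW = C;
      CW.each_col() %= lam.col(t);
      D.slice(t) = Dp + C.t() * CW;
    }
  };

  while (true) {
    fill_grad_hess(X);
    gnorm = abs(G).max();
    if (gnorm < grad_tol) { converged = true; break; }
    if (iter >= max_iter) break;
    ++iter;
    // forward Schur factorisation + solve H Z = G
    Phi.slice(0) = D.slice(0);
    Cvec.col(0) = G.col(0);
    for (uword t = 1; t < T; ++t) {
      mat M = solve(Phi.slice(t - 1), U, solve_opts::likely_sympd);
      Phi.slice(t) = D.slice(t) - U.t() * M;
      Cvec.col(t) = G.col(t) - M.t() * Cvec.col(t - 1);
    }
    Z.col(T - 1) = solve(Phi.slice(T - 1), Cvec.col(T - 1), solve_opts::likely_sympd);
    for (uword t = T - 1; t-- > 0; ) {
      Z.col(t) = solve(Phi.slice(t), Cvec.col(t) - U * Z.col(t + 1),
                       solve_opts::likely_sympd);
    }
    double descent = accu(G % Z);
    double alpha = 1.0, f_new = f;
    mat X_new;
    while (true) {
      X_new = X - alpha * Z;
      f_new = neg_logjoint(X_new, Y, A, Q0i, Qi, C, d, x0, const_term);
      if (f_new <= f - 1e-4 * alpha * descent || alpha < 1e-10) break;
      alpha *= 0.5;
    }
    // line-search stall at the arithmetic floor: accept the mode if the
    // gradient is already far below any practical scale
    if (f - f_new < 1e-12 * (1.0 + std::abs(f)) && gnorm < 1e-5) {
      if (f_new < f) { X = X_new; f = f_new; }
      converged = true;
      break;
    }
    X = X_new;
    f = f_new;
  }

  // factorise at the mode for evidence and covariances
  fill_grad_hess(X);
  Phi.slice(0) = D.slice(0);
  double logdetH = 0.0;
  for (uword t = 0; t < T; ++t) {
    if (t > 0) {
      mat M = solve(Phi.slice(t - 1), U, solve_opts::likely_sympd);
      Phi.slice(t) = D.slice(t) - U.t() * M;
    }
    double ld;
    log_det(ld, sign, Phi.slice(t));
    logdetH += ld;
  }
  double loglik = -f + 0.5 * (double)(p * T) * std::log(2.0 * datum::pi) -
                  0.5 * logdetH;

  Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("mean") = X,
      Rcpp::Named("loglik") = loglik,
      Rcpp::Named("logdetH") = logdetH,
      Rcpp::Named("grad_norm") = gnorm,
      Rcpp::Named("iterations") = iter,
      Rcpp::Named("converged") = converged);

  if (want_cov) {
    cube Sigma(p, p, T);
    cube Cross(p, p, T > 1 ? T - 1 : 1);
    Sigma.slice(T - 1) = inv_sympd(symmatu(Phi.slice(T - 1)));
    for (uword t = T - 1; t-- > 0; ) {
      mat Pinv = inv_sympd(symmatu(Phi.slice(t)));
      mat M = Pinv * U;
      Cross.slice(t) = -M * Sigma.slice(t + 1);
      mat S = Pinv + M * Sigma.slice(t + 1) * M.t();
      Sigma.slice(t) = symmatu(0.5 * (S + S.t()));
    }
    out["Sigma"] = Sigma;
    out["Cross"] = Cross;
  }
  return out;
}
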