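// Lawson-Hanson active-set non-negative least squares, plus the
// Tikhonov-regularized variant with the regularization weight chosen by
// bisection so the data misfit lands in a prescribed window above the
// unregularized minimum (the standard smoothing strategy for multi-echo
// T2 spectrum estimation).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

vec nnls_solve(const mat &A, const vec &b, int max_iter = 0) {
  const uword n = A.n_cols;
  if (max_iter <= 0) max_iter = 3 * (int)n + 30;
  vec x(n, fill::zeros);
  std::vector<uword> P;
  uvec inP(n, fill::zeros);
  vec w = A.t() * (b - A * x);
  const double tol = 10.0 * datum::eps * norm(A, 1) * std::max(A.n_rows, n);
  int outer = 0;
  while (outer++ < max_iter) {
    // most-violating inactive coefficient
    double wmax = tol; sword jmax = -1;
    for (uword j = 0; j < n; ++j)
      if (!inP[j] && w[j] > wmax) { wmax = w[j]; jmax = j; }
    if (jmax < 0) break;
    inP[jmax] = 1; P.push_back((uword)jmax);
    for (;;) {
      uvec Pidx(P.size());
      for (size_t t = 0; t < P.size(); ++t) Pidx[t] = P[t];
      vec z;
      bool ok = solve(z, A.cols(Pidx), b, solve_opts::fast);
      if (!ok) z = pinv(A.cols(Pidx)) * b;
      if (z.min() > 0) {
        x.zeros();
        for (size_t t = 0; t < P.size(); ++t) x[P[t]] = z[t];
        break;
      }
      // step toward z until the first coefficient hits zero; drop it
      double alpha = datum::inf;
      for (size_t t = 0; t < P.size(); ++t)
        if (z[t] <= 0) {
          double a = x[P[t]] / (x[P[t]] - z[t]);
          if (a < alpha) alpha = a;
        }
      for (size_t t = 0; t < P.size(); ++t)
        x[P[t]] += alpha * (z[t] - x[P[t]]);
      std::vector<uword> keep;
      for (size_t t = 0; t < P.size(); ++t) {
        if (x[P[t]] > tol) keep.push_back(P[t]);
        else { x[P[t]] = 0.0; inP[P[t]] = 0; }
      }
      P = keep;
      if (P.empty()) { x.zeros(); break; }
    }
    w = A.t() * (b - A * x);
  }
  return x;
}

// [[Rcpp::export]]
Rcpp::List nnls_cpp(const arma::mat &A, const arma::vec &b) {
  vec x = nnls_solve(A, b);
  double rss = accu(square(A * x - b));
  return Rcpp::List::create(Rcpp::Named("x") = x, Rcpp::Named("rss") = rss);
}

// misfit chi2 (data term only) of the mu-regularized solution
static double reg_chi2(const mat &A, const vec &b, double mu, vec &x) {
  const uword m = A.n_rows, n = A.n_cols;
  mat Aa(m + n, n, fill::zeros);
  Aa.rows(0, m - 1) = A;
  Aa.rows(m, m + n - 1).diag() += std::sqrt(mu);
  vec ba(m + n, fill::zeros);
  ba.subvec(0, m - 1) = b;
  x = nnls_solve(Aa, ba);
  return accu(square(A * x - b));
}

// [[Rcpp::export]]
Rcpp::List regnnls_cpp(const arma::mat &A, const arma::vec &b,
                       double chi2_low, double chi2_high) {
  vec x0 = nnls_solve(A, b);
  double chi2_min = accu(square(A * x0 - b));
  // noiseless / perfectly representable signal: no room to regularize
  if (chi2_min <= 1e-12 * std::max(1.0, accu(square(b)))) {
    return Rcpp::List::create(
      Rcpp::Named("x") = x0, Rcpp::Named("mu") = 0.0,
      Rcpp::Named("chi2") = chi2_min, Rcpp::Named("chi2_min") = chi2_min,
      Rcpp::Named("fallback") = true);
  }
  // Smallest mu whose misfit reaches the window: bisect in log(mu) on the
  // crossing of the window's low edge (chi2 is continuous and
  // non-decreasing in mu, so the crossing lands inside [low, high]).
  const double lo_t = chi2_low * chi2_min, hi_t = chi2_high * chi2_min;
  vec x;
  double mu_hi = 1e-8, c_hi = reg_chi2(A, b, mu_hi, x);
  int guard = 0;
  while (c_hi < lo_t && guard++ < 40) { mu_hi *= 10.0; c_hi = reg_chi2(A, b, mu_hi, x); }
  double mu_lo = mu_hi / 10.0;
  for (int it = 0; it < 60 && mu_hi / mu_lo > 1.02; ++it) {
    double mu_m = std::sqrt(mu_lo * mu_hi);
    double c_m = reg_chi2(A, b, mu_m, x);
    if (c_m >= lo_t) mu_hi = mu_m; else mu_lo = mu_m;
  }
  double mu = mu_hi;
  double chi2 = reg_chi2(A, b, mu, x);
  bool in_window = (chi2 >= lo_t && chi2 <= hi_t);
  if (!in_window) { // window unattainable; return unregularized fit
    x = x0; mu = 0.0; chi2 = chi2_min;
  }
  return Rcpp::List::create(
    Rcpp::Named("x") = x, Rcpp::Named("mu") = mu,
    Rcpp::Named("chi2") = chi2, Rcpp::Named("chi2_min") = chi2_min,
    Rcpp::Named("fallback") = !in_window);
}
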