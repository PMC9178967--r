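// Batched voxelwise myelin-water fit: flip-angle estimation on a coarse
// T2 grid (stimulated-echo correction), EPG basis at the refined angle,
// regularized NNLS spectrum, then MWF and geometric mean T2 summaries.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

arma::vec nnls_solve(const arma::mat &A, const arma::vec &b, int max_iter = 0);
arma::vec epg_echo_train_cpp(double t2_ms, double t1_ms, double esp_ms,
                             int n_echoes, double flip_deg);
arma::mat epg_basis_cpp(const arma::vec &t2_ms, double t1_ms, double esp_ms,
                        int n_echoes, double flip_deg);

// Lawson-Hanson on the normal equations: G = A'A (+ mu I), Atb = A'b.
// Returns x; the data-term misfit is b'b - 2 x'A'b + x'(A'A)x, computed by
// the caller from the unshifted Gram matrix.
static vec nnls_gram(const mat &G, const vec &Atb) {
  const uword n = G.n_cols;
  const int max_iter = 3 * (int)n + 30;
  vec x(n, fill::zeros);
  std::vector<uword> P;
  uvec inP(n, fill::zeros);
  vec w = Atb; // gradient of -0.5 objective at x = 0
  const double tol = 10.0 * datum::eps * norm(G, 1) * n;
  int outer = 0;
  while (outer++ < max_iter) {
    double wmax = tol; sword jmax = -1;
    for (uword j = 0; j < n; ++j)
      if (!inP[j] && w[j] > wmax) { wmax = w[j]; jmax = j; }
    if (jmax < 0) break;
    inP[jmax] = 1; P.push_back((uword)jmax);
    for (;;) {
      uvec Pidx(P.size());
      for (size_t t = 0; t < P.size(); ++t) Pidx[t] = P[t];
      vec z;
      bool ok = solve(z, G.submat(Pidx, Pidx), Atb.elem(Pidx),
                      solve_opts::likely_sympd);
      if (!ok) z = pinv(G.submat(Pidx, Pidx)) * Atb.elem(Pidx);
      if (z.min() > 0) {
        x.zeros();
        for (size_t t = 0; t < P.size(); ++t) x[P[t]] = z[t];
        break;
      }
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
    w = Atb - G * x;
  }
  return x;
}

static double misfit_gram(const mat &G0, const vec &Atb, double btb,
                          const vec &x) {
  return btb - 2.0 * dot(x, Atb) + dot(x, G0 * x);
}

// [[Rcpp::export]]
Rcpp::List mwi_fit_batch_cpp(const arma::mat &signals, // n_echoes x n_vox
                             const arma::vec &t2_grid,
                             const arma::vec &coarse_grid,
                             const arma::vec &angle_grid,
                             double esp_ms, double t1_ms,
                             double chi2_low, double chi2_high,
                             double mwf_lo, double mwf_hi,
                             double gmt2_lo, double gmt2_hi,
                             bool return_spectra) {
  const int n_echoes = signals.n_rows;
  const uword n_vox = signals.n_cols;
  const uword n_ang = angle_grid.n_elem;

  // angle-search bases are voxel independent: precompute once
  std::vector<mat> coarse_bases(n_ang);
  for (uword a = 0; a < n_ang; ++a)
    coarse_bases[a] = epg_basis_cpp(coarse_grid, t1_ms, esp_ms, n_echoes, angle_grid[a]);

  uvec in_mwf = find(t2_grid >= mwf_lo && t2_grid <= mwf_hi);
  uvec in_gm  = find(t2_grid >= gmt2_lo && t2_grid <= gmt2_hi);
  vec logt2 = log(t2_grid);

  vec mwf(n_vox, fill::value(datum::nan)), gmt2(n_vox, fill::value(datum::nan));
  vec flip(n_vox, fill::value(datum::nan)), chi2(n_vox, fill::value(datum::nan));
  vec mu(n_vox, fill::value(datum::nan));
  ivec flag(n_vox, fill::zeros); // 0 ok, 1 low-confidence flip, 2 rejected, 3 reg fallback
  mat spectra;
  if (return_spectra) spectra.zeros(t2_grid.n_elem, n_vox);

  // Gram matrices of the coarse angle-search bases, precomputed once
  std::vector<mat> coarse_G(n_ang);
  for (uword a = 0; a < n_ang; ++a)
    coarse_G[a] = coarse_bases[a].t() * coarse_bases[a];

  for (uword v = 0; v < n_vox; ++v) {
    vec s = signals.col(v);
    if (!s.is_finite() || s.max() <= 0) { flag[v] = 2; continue; }
    double scale = s.max();
    vec sn = s / scale;
    double btb = dot(sn, sn);

    // flip-angle search: NNLS residual over the angle grid, coarse spectrum
    vec res(n_ang);
    for (uword a = 0; a < n_ang; ++a) {
      vec Atb = coarse_bases[a].t() * sn;
      vec xa = nnls_gram(coarse_G[a], Atb);
      res[a] = misfit_gram(coarse_G[a], Atb, btb, xa);
    }
    double rmax = res.max(), rmin = res.min();
    double fa;
    if (rmax <= 0 || (rmax - rmin) / rmax < 1e-6) {
      fa = 180.0; flag[v] = 1; // flat residual profile: pure-noise voxel
    } else {
      uword i0 = res.index_min();
      fa = angle_grid[i0];
      if (i0 > 0 && i0 + 1 < n_ang) { // parabolic refinement
        double y1 = res[i0 - 1], y2 = res[i0], y3 = res[i0 + 1];
        double denom = y1 - 2.0 * y2 + y3;
        if (denom > 0) {
          double h = angle_grid[i0 + 1] - angle_grid[i0];
          double shift = 0.5 * (y1 - y3) / denom;
          if (std::abs(shift) <= 1.0) fa += shift * h;
        }
      }
      if (fa > 180.0) fa = 180.0;
      if (fa < angle_grid.min()) fa = angle_grid.min();
    }
    flip[v] = fa;

    mat B = epg_basis_cpp(t2_grid, t1_ms, esp_ms, n_echoes, fa);
    mat G0 = B.t() * B;
    vec Atb = B.t() * sn;
    auto reg_fit = [&](double mu, vec &xx) {
      mat G = G0; G.diag() += mu;
      xx = nnls_gram(G, Atb);
      return misfit_gram(G0, Atb, btb, xx);
    };

    vec x0 = nnls_gram(G0, Atb);
    double chi2_min = misfit_gram(G0, Atb, btb, x0);
    vec x; double muv, c2;
    if (chi2_min <= 1e-12 * std::max(1.0, btb)) {
      x = x0; muv = 0.0; c2 = chi2_min; if (flag[v] == 0) flag[v] = 3;
    } else {
      // smallest mu reaching the misfit window (see regnnls_cpp)
      const double lo_t = chi2_low * chi2_min, hi_t = chi2_high * chi2_min;
      double mu_hi = 1e-8, c_hi = reg_fit(mu_hi, x);
      int guard = 0;
      while (c_hi < lo_t && guard++ < 40) { mu_hi *= 10.0; c_hi = reg_fit(mu_hi, x); }
      double mu_lo = mu_hi / 10.0;
      for (int it = 0; it < 60 && mu_hi / mu_lo > 1.02; ++it) {
        double mu_m = std::sqrt(mu_lo * mu_hi);
        double c_m = reg_fit(mu_m, x);
        if (c_m >= lo_t) mu_hi = mu_m; else mu_lo = mu_m;
      }
      muv = mu_hi;
      c2 = reg_fit(muv, x);
      if (!(c2 >= lo_t && c2 <= hi_t)) { x = x0; muv = 0.0; c2 = chi2_min; if (flag[v] == 0) flag[v] = 3; }
    }
    mu[v] = muv;
    chi2[v] = c2 * scale * scale;

    double tot = accu(x);
    if (tot > 0) mwf[v] = accu(x.elem(in_mwf)) / tot;
    double wsum = accu(x.elem(in_gm));
    if (wsum > 0) gmt2[v] = std::exp(accu(x.elem(in_gm) % logt2.elem(in_gm)) / wsum);
    if (return_spectra) spectra.col(v) = x * scale;
  }

  Rcpp::List out = Rcpp::List::create(
    Rcpp::Named("mwf") = mwf, Rcpp::Named("gmt2") = gmt2,
    Rcpp::Named("flip") = flip, Rcpp::Named("chi2") = chi2,
    Rcpp::Named("mu") = mu, Rcpp::Named("flag") = flag);
  if (return_spectra) out["spectra"] = spectra;
  return out;
}
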