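// Extended phase graph (EPG) simulation of a CPMG multi-echo spin-echo train.
//
// Configuration states (F+, F-, Z) are propagated through the refocusing
// train with T2/T1 relaxation over each half echo-spacing and one crusher
// dephasing shift per half interval.  Refocusing pulses are applied about
// the y axis (CPMG condition), under which the state vectors stay real.
// Longitudinal regrowth of Z0 is ignored (unit-amplitude decay basis).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static void epg_shift(vec &Fp, vec &Fm) {
  const int K = Fp.n_elem;
  for (int k = K - 1; k >= 1; --k) Fp[k] = Fp[k - 1];
  Fp[0] = Fm[1];              // F(-1) moves into F(0); states are real here
  for (int k = 0; k < K - 1; ++k) Fm[k] = Fm[k + 1];
  Fm[K - 1] = 0.0;
}

// [[Rcpp::export]]
arma::vec epg_echo_train_cpp(double t2_ms, double t1_ms, double esp_ms,
                             int n_echoes, double flip_deg) {
  const int K = n_echoes + 2;
  vec Fp(K, fill::zeros), Fm(K, fill::zeros), Z(K, fill::zeros);
  Fp[0] = 1.0; // transverse magnetization right after excitation

  const double a  = flip_deg * datum::pi / 180.0;
  const double c2 = std::cos(a / 2.0) * std::cos(a / 2.0);
  const double s2 = std::sin(a / 2.0) * std::sin(a / 2.0);
  const double sa = std::sin(a);
  const double E2 = std::exp(-0.5 * esp_ms / t2_ms);
  const double E1 = std::exp(-0.5 * esp_ms / t1_ms);

  vec echoes(n_echoes, fill::zeros);
  for (int n = 0; n < n_echoes; ++n) {
    // first half interval: relaxation then crusher dephasing
    Fp *= E2; Fm *= E2; Z *= E1;
    epg_shift(Fp, Fm);
    // refocusing pulse (CPMG phase); Z holds the imaginary part of the
    // longitudinal configuration states, which keeps all vectors real
    vec Fp2 = c2 * Fp + s2 * Fm + sa * Z;
    vec Fm2 = s2 * Fp + c2 * Fm - sa * Z;
    vec Z2  = -0.5 * sa * Fp + 0.5 * sa * Fm + std::cos(a) * Z;
    Fp = Fp2; Fm = Fm2; Z = Z2;
    // second half interval
    Fp *= E2; Fm *= E2; Z *= E1;
    epg_shift(Fp, Fm);
    echoes[n] = std::abs(Fp[0]);
  }
  return echoes;
}

// [[Rcpp::export]]
arma::mat epg_basis_cpp(const arma::vec &t2_ms, double t1_ms, double esp_ms,
                        int n_echoes, double flip_deg) {
  mat B(n_echoes, t2_ms.n_elem);
  for (uword j = 0; j < t2_ms.n_elem; ++j)
    B.col(j) = epg_echo_train_cpp(t2_ms[j], t1_ms, esp_ms, n_echoes, flip_deg);
  return B;
}

// two-pool decay for many voxels at once (phantom signal generation)
// [[Rcpp::export]]
arma::mat epg_two_pool_batch_cpp(const arma::vec &mwf, const arma::vec &ie_t2,
                                 const arma::vec &flip, double myelin_t2,
                                 double t1_ms, double esp_ms, int n_echoes) {
  const uword n = mwf.n_elem;
  mat out(n_echoes, n);
  for (uword v = 0; v < n; ++v) {
    vec my = epg_echo_train_cpp(myelin_t2, t1_ms, esp_ms, n_echoes, flip[v]);
    vec ie = epg_echo_train_cpp(ie_t2[v], t1_ms, esp_ms, n_echoes, flip[v]);
    out.col(v) = mwf[v] * my + (1.0 - mwf[v]) * ie;
  }
  return out;
}
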