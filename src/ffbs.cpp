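#include <Rcpp.h>
using namespace Rcpp;

// Forward-filtering backward-sampling for N independent scalar AR(1)
// state-space models sharing rho and the observation variance:
//
//   state k:  w_t = rho * w_{t-1} + eta_t,  eta_t ~ N(0, sig2w * lam_k)
//   obs:      y_t = w_t + e_t,              e_t   ~ N(0, sig2e)
//   init:     w_1 ~ N(0, sig2w * lam_k / (1 - rho^2))
//
// This is the latent-process update of the spatio-temporal model after
// rotating into the eigenbasis of the spatial correlation matrix (lam are
// its eigenvalues), which decouples the N-dimensional Kalman recursions.
// znorm supplies the standard-normal draws (generated in R for seed
// reproducibility). ytil, znorm and the result are N x T.
// [[Rcpp::export]]
NumericMatrix ffbs_scalar_ar1(const NumericMatrix& ytil,
                              const NumericVector& lam,
                              double rho, double sig2w, double sig2e,
                              const NumericMatrix& znorm) {
  const int N = ytil.nrow(), T = ytil.ncol();
  NumericMatrix w(N, T);
  std::vector<double> m(T), P(T);
  for (int k = 0; k < N; ++k) {
    const double q = sig2w * lam[k];
    // forward filter
    double mPrev = 0.0, PPrev = q / (1.0 - rho * rho);
    for (int t = 0; t < T; ++t) {
      double mPred, PPred;
      if (t == 0) { mPred = mPrev; PPred = PPrev; }
      else { mPred = rho * m[t - 1]; PPred = rho * rho * P[t - 1] + q; }
      const double K = PPred / (PPred + sig2e);
      m[t] = mPred + K * (ytil(k, t) - mPred);
      P[t] = (1.0 - K) * PPred;
    }
    // backward sample
    w(k, T - 1) = m[T - 1] + std::sqrt(P[T - 1]) * znorm(k, T - 1);
    for (int t = T - 2; t >= 0; --t) {
      const double denom = rho * rho * P[t] + q;
      const double J = (denom > 0.0) ? rho * P[t] / denom : 0.0;
      const double h = m[t] + J * (w(k, t + 1) - rho * m[t]);
      double V = P[t] - J * J * denom;
      if (V < 0.0) V = 0.0;
      w(k, t) = h + std::sqrt(V) * znorm(k, t);
    }
  }
  return w;
}

// Sufficient statistics for the trend-coefficient update with the latent
// process integrated out. In the eigenbasis, component k observes
//   ytil_k ~ N(c_k * X beta, Sigma_k),
//   Sigma_k = sig2e * I + q_k * P^{-1},  q_k = sig2w * lam_k,
// with P the tridiagonal AR(1) precision pattern (unit innovation variance).
// Since G_k = sig2e * P + q_k * I commutes with P,
//   Sigma_k^{-1} = P * G_k^{-1},
// so each component needs one tridiagonal factorisation and O(T) solves.
// Returns A = sum_k c_k^2 X' Sigma_k^{-1} X and b = sum_k c_k X' Sigma_k^{-1} y_k.
// [[Rcpp::export]]
List beta_marg_suffstats(const NumericMatrix& X, const NumericMatrix& ytil,
                         const NumericVector& lam, const NumericVector& cvec,
                         double rho, double sig2w, double sig2e) {
  const int T = X.nrow(), p = X.ncol(), N = ytil.nrow();
  NumericMatrix A(p, p);
  NumericVector b(p);
  std::vector<double> Pd(T), cfac(T), dfac(T);
  std::vector<double> U((p + 1) * T);  // G^{-1} [X, y_k], column-major
  std::vector<double> PU((p + 1) * T); // P * U

  Pd[0] = 1.0; Pd[T - 1] = 1.0;
  for (int t = 1; t < T - 1; ++t) Pd[t] = 1.0 + rho * rho;
  const double Pe = -rho; // off-diagonal of P

  for (int k = 0; k < N; ++k) {
    const double q = sig2w * lam[k];
    const double ck = cvec[k];
    const double Ge = sig2e * Pe;
    // Thomas factorisation of G = sig2e * P + q I
    dfac[0] = sig2e * Pd[0] + q;
    for (int t = 1; t < T; ++t) {
      cfac[t] = Ge / dfac[t - 1];
      dfac[t] = sig2e * Pd[t] + q - cfac[t] * Ge;
    }
    // solves for X columns and ytil row k
    for (int j = 0; j <= p; ++j) {
      double* u = &U[j * T];
      for (int t = 0; t < T; ++t) {
        const double rhs = (j < p) ? X(t, j) : ytil(k, t);
        u[t] = rhs - (t > 0 ? cfac[t] * u[t - 1] : 0.0);
      }
      u[T - 1] /= dfac[T - 1];
      for (int t = T - 2; t >= 0; --t) u[t] = (u[t] - Ge * u[t + 1]) / dfac[t];
      // multiply by P
      double* pu = &PU[j * T];
      for (int t = 0; t < T; ++t) {
        pu[t] = Pd[t] * u[t] + Pe * ((t > 0 ? u[t - 1] : 0.0) +
                                     (t < T - 1 ? u[t + 1] : 0.0));
      }
    }
    // accumulate A += ck^2 X' (P G^{-1} X), b += ck X' (P G^{-1} y_k)
    for (int j = 0; j < p; ++j) {
      const double* puj = &PU[j * T];
      for (int i = 0; i < p; ++i) {
        double s = 0.0;
        for (int t = 0; t < T; ++t) s += X(t, i) * puj[t];
        A(i, j) += ck * ck * s;
      }
    }
    const double* puy = &PU[p * T];
    for (int i = 0; i < p; ++i) {
      double s = 0.0;
      for (int t = 0; t < T; ++t) s += X(t, i) * puy[t];
      b[i] += ck * s;
    }
  }
  return List::create(Named("A") = A, Named("b") = b);
}
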