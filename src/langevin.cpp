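#include <Rcpp.h>
using namespace Rcpp;

// Hill exponents are 1 or 2 in practice; avoid std::pow on that fast path.
static inline double hillpow(double x, double n) {
  if (n == 2.0) return x * x;
  if (n == 1.0) return x;
  return std::pow(x, n);
}

// Euler-Maruyama integration of the five-species cascade for an ensemble of
// cells, with additive noise on each synthesis term and reflection at zero.
// The drift mirrors rhs_matrix() on the R side; the two are pinned against
// each other in the test suite. Uses R's RNG so results are reproducible
// under set.seed().
//
// S0: n_cells x 5 matrix (columns L, R, K, N, F). Returns the state matrix
// after n_steps steps of size dt.
// [[Rcpp::export]]
NumericMatrix langevin_paths(NumericMatrix S0, double c_o2, List params,
                             LogicalVector functional, double sigma,
                             int n_steps, double dt) {
  const double K_L = params["K_L"], n_L = params["n_L"];
  const double K_NO2 = params["K_NO2"], n_NO2 = params["n_NO2"];
  const double beta_L = params["beta_L"], beta_R = params["beta_R"];
  const double alpha_K = params["alpha_K"], beta_K = params["beta_K"];
  const double alpha_N = params["alpha_N"], beta_N = params["beta_N"];
  const double alpha_F = params["alpha_F"], beta_F = params["beta_F"];
  const double delta = params["delta"], K_RK = params["K_RK"];
  const double A_K = params["A_K_dist"], A_N = params["A_N_dist"];
  const double A_Kf = params["A_K_fix"], A_Nf = params["A_N_fix"];
  const double rho_K = params["rho_K"], rho_N = params["rho_N"];
  const double n_DNA = params["n_DNA"];
  const bool f_hfixl = functional[0], f_fxkr = functional[1],
             f_fixk = functional[2], f_fnrn = functional[3];

  const double aL = std::pow(K_L, n_L) /
                    (std::pow(K_L, n_L) + std::pow(c_o2, n_L));
  const double aN = std::pow(K_NO2, n_NO2) /
                    (std::pow(K_NO2, n_NO2) + std::pow(c_o2, n_NO2));
  const double sq = sigma * std::sqrt(dt);

  const int n = S0.nrow();
  NumericMatrix S = clone(S0);
  for (int step = 0; step < n_steps; ++step) {
    for (int i = 0; i < n; ++i) {
      double L = S(i, 0), R = S(i, 1), K = S(i, 2), N = S(i, 3), F = S(i, 4);
      double Ra = (L * delta / beta_L) * R * aL;
      double Na = N * aN;
      double xK = hillpow(K / A_K, n_DNA);
      double yN = hillpow(Na / A_N, n_DNA);
      double th_d = (xK + yN) / (1.0 + xK + yN);
      double xKp = hillpow(K / (rho_K * A_K), n_DNA);
      double yNp = hillpow(Na / (rho_N * A_N), n_DNA);
      double th_p = (xKp + yNp) / (1.0 + xKp + yNp);
      double xKf = hillpow(K / A_Kf, n_DNA);
      double yNf = hillpow(Na / A_Nf, n_DNA);
      double th_f = (xKf + yNf) / (1.0 + xKf + yNf);
      double dL = (f_hfixl ? beta_L : 0.0) - delta * L;
      double dR = (f_fxkr ? beta_R : 0.0) - delta * R;
      double dK = (f_fixk ? alpha_K + beta_K * Ra / (K_RK + Ra) : 0.0) -
                  delta * K;
      double dN = (f_fnrn ? alpha_N + beta_N * th_d * (1.0 - th_p) : 0.0) -
                  delta * N;
      double dF = alpha_F + beta_F * th_f - delta * F;
      L += dt * dL; R += dt * dR; K += dt * dK; N += dt * dN; F += dt * dF;
      if (sigma > 0.0) {
        L += sq * norm_rand(); R += sq * norm_rand(); K += sq * norm_rand();
        N += sq * norm_rand(); F += sq * norm_rand();
      }
      S(i, 0) = std::fabs(L); S(i, 1) = std::fabs(R);
      S(i, 2) = std::fabs(K); S(i, 3) = std::fabs(N);
      S(i, 4) = std::fabs(F);
    }
    if (step % 1000 == 0) Rcpp::checkUserInterrupt();
  }
  return S;
}
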