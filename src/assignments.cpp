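#include <Rcpp.h>
using namespace Rcpp;

// Step-1 inner loop: draw S_i from P(S_i = k) proportional to
// eta_k * f_N(y_i | mu_k, sigma2_k), evaluated in log space per
// observation. Uses R's RNG so draws are reproducible under set.seed().
// [[Rcpp::export(name = ".sample_assignments")]]
IntegerVector sample_assignments(NumericVector y, NumericVector eta,
                                 NumericVector mu, NumericVector sigma2) {
  const int n = y.size(), K = eta.size();
  std::vector<double> a(K), b(K), c(K);
  for (int k = 0; k < K; ++k) {
    a[k] = -0.5 / sigma2[k];
    b[k] = mu[k] / sigma2[k];
    c[k] = (eta[k] > 0 ? std::log(eta[k]) : R_NegInf) -
           0.5 * mu[k] * mu[k] / sigma2[k] - 0.5 * std::log(sigma2[k]);
  }
  IntegerVector S(n);
  std::vector<double> logp(K), p(K);
  for (int i = 0; i < n; ++i) {
    const double yi = y[i], y2 = yi * yi;
    double m = R_NegInf;
    for (int k = 0; k < K; ++k) {
      logp[k] = a[k] * y2 + b[k] * yi + c[k];
      if (logp[k] > m) m = logp[k];
    }
    if (!R_FINITE(m))
      stop("categorical weights underflowed for observation %d; "
           "state is numerically degenerate", i + 1);
    double tot = 0.0;
    for (int k = 0; k < K; ++k) {
      // exp(-45) ~ 3e-20: relative mass below double precision of the
      // normalising sum, and skipping it avoids slow subnormal exp calls
      const double d = logp[k] - m;
      p[k] = (d > -45.0) ? std::exp(d) : 0.0;
      tot += p[k];
    }
    const double u = unif_rand() * tot;
    double acc = 0.0;
    int s = K;
    for (int k = 0; k < K; ++k) {
      acc += p[k];
      if (u <= acc) { s = k + 1; break; }
    }
    S[i] = s;
  }
  return S;
}
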