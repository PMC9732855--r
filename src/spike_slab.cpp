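#include <Rcpp.h>
using namespace Rcpp;

// Gibbs sampler for the spike-and-slab regression y = X b + e with
// b_j ~ pi N(0, sb2) + (1 - pi) delta_0, Beta(1,1) prior on pi,
// inverse-gamma updates for the slab and noise variances. Uses R's RNG so
// results are reproducible under set.seed(). Returns the posterior mean
// of b over the kept iterations.
// [[Rcpp::export(name = ".spike_slab_gibbs")]]
NumericVector spike_slab_gibbs(const NumericMatrix& X,
                               const NumericVector& y,
                               int n_iter, int burn,
                               double sb2_init, double pi_init) {
  const int n = X.nrow(), m = X.ncol();

  // precompute X'X and X'y
  NumericMatrix XtX(m, m);
  NumericVector Xty(m);
  for (int j = 0; j < m; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += X(i, j) * y[i];
    Xty[j] = s;
    for (int k = j; k < m; ++k) {
      double t = 0.0;
      for (int i = 0; i < n; ++i) t += X(i, j) * X(i, k);
      XtX(j, k) = t;
      XtX(k, j) = t;
    }
  }

  NumericVector b(m, 0.0), bsum(m, 0.0);
  std::vector<int> gam(m, 0);
  double sigma2 = 1.0, sb2 = sb2_init, pi_inc = pi_init;
  int kept = 0;
  RNGScope scope;

  for (int it = 0; it < n_iter; ++it) {
    for (int j = 0; j < m; ++j) {
      double rj = Xty[j];
      for (int k = 0; k < m; ++k)
        if (k != j) rj -= XtX(j, k) * b[k];
      double v_post = 1.0 / (XtX(j, j) / sigma2 + 1.0 / sb2);
      double m_post = v_post * rj / sigma2;
      double lbf = 0.5 * std::log(v_post / sb2) +
                   0.5 * m_post * m_post / v_post;
      double lo = lbf + std::log(pi_inc / (1.0 - pi_inc));
      double p1 = 1.0 / (1.0 + std::exp(-lo));
      gam[j] = R::runif(0.0, 1.0) < p1 ? 1 : 0;
      b[j] = gam[j] ? R::rnorm(m_post, std::sqrt(v_post)) : 0.0;
    }
    int k_inc = 0;
    double ssb = 0.0;
    for (int j = 0; j < m; ++j)
      if (gam[j]) { ++k_inc; ssb += b[j] * b[j]; }
    pi_inc = R::rbeta(1.0 + k_inc, 1.0 + m - k_inc);
    if (pi_inc < 1e-3) pi_inc = 1e-3;
    if (pi_inc > 1.0 - 1e-3) pi_inc = 1.0 - 1e-3;
    if (k_inc > 0) {
      sb2 = 1.0 / R::rgamma(1.0 + k_inc / 2.0, 1.0 / (0.1 + ssb / 2.0));
      if (sb2 < 1e-6) sb2 = 1e-6;
    }
    double sse = 0.0;
    for (int i = 0; i < n; ++i) {
      double fit = 0.0;
      for (int j = 0; j < m; ++j)
        if (b[j] != 0.0) fit += X(i, j) * b[j];
      double r = y[i] - fit;
      sse += r * r;
    }
    sigma2 = 1.0 / R::rgamma(1.0 + n / 2.0, 1.0 / (1.0 + sse / 2.0));
    if (it >= burn) {
      for (int j = 0; j < m; ++j) bsum[j] += b[j];
      ++kept;
    }
  }
  for (int j = 0; j < m; ++j) bsum[j] /= kept;
  return bsum;
}
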