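#include <Rcpp.h>
using namespace Rcpp;

// Scaled inverse chi-square draw: df * scale / chisq(df)
static inline double rscinvchisq(double df, double scale) {
  return df * scale / R::rchisq(df);
}

// Gibbs sampler for BayesB: marker effects from a mixture of a point mass at
// zero (prior probability pi_zero) and a normal with per-marker variance
// carrying a scaled-inverse-chi-square prior. Uses R's RNG, so the chain is
// reproducible through set.seed() on the R side.
// [[Rcpp::export(name = ".bayesb_gibbs")]]
List bayesb_gibbs(NumericVector y, NumericMatrix W, int n_iter, int burn_in,
                  int thin, double pi_zero, double df0, double S0,
                  double dfe0, double Se0) {
  const int n = W.nrow(), m = W.ncol();
  NumericVector beta(m, 0.0), sj(m, S0), cj(m);
  NumericVector beta_sum(m, 0.0), incl_sum(m, 0.0);
  double mu = mean(y), mu_sum = 0.0, ve_sum = 0.0;
  double ve = var(noNA(y)) * 0.5;
  if (ve <= 0) ve = 1e-6;
  NumericVector r(n);
  for (int i = 0; i < n; ++i) r[i] = y[i] - mu;
  for (int j = 0; j < m; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += W(i, j) * W(i, j);
    cj[j] = s;
  }
  int n_saved = 0;
  for (int it = 0; it < n_iter; ++it) {
    // intercept
    double rs = 0.0;
    for (int i = 0; i < n; ++i) rs += r[i] + mu;
    double mu_new = R::rnorm(rs / n, std::sqrt(ve / n));
    for (int i = 0; i < n; ++i) r[i] += mu - mu_new;
    mu = mu_new;
    // marker effects
    for (int j = 0; j < m; ++j) {
      if (cj[j] <= 0) { beta[j] = 0.0; continue; }
      double rj = 0.0;
      const double bold = beta[j];
      for (int i = 0; i < n; ++i) rj += W(i, j) * r[i];
      rj += cj[j] * bold;
      // inclusion indicator with the effect integrated out
      double v1 = cj[j] * sj[j] + ve;
      double logBF = -0.5 * std::log(v1 / ve) +
        0.5 * rj * rj * sj[j] / (ve * v1);
      double p1 = (1.0 - pi_zero) /
        ((1.0 - pi_zero) + pi_zero * std::exp(-logBF));
      double bnew = 0.0;
      bool in_model = R::unif_rand() < p1;
      if (in_model) {
        double denom = cj[j] + ve / sj[j];
        bnew = R::rnorm(rj / denom, std::sqrt(ve / denom));
      }
      if (bnew != bold)
        for (int i = 0; i < n; ++i) r[i] += W(i, j) * (bold - bnew);
      beta[j] = bnew;
      // per-marker variance
      if (in_model)
        sj[j] = rscinvchisq(df0 + 1.0, (df0 * S0 + bnew * bnew) / (df0 + 1.0));
      else
        sj[j] = rscinvchisq(df0, S0);
      if (it >= burn_in && ((it - burn_in) % thin == 0)) {
        beta_sum[j] += bnew;
        if (in_model) incl_sum[j] += 1.0;
      }
    }
    // residual variance
    double sse = 0.0;
    for (int i = 0; i < n; ++i) sse += r[i] * r[i];
    ve = rscinvchisq(dfe0 + n, (sse + dfe0 * Se0) / (dfe0 + n));
    if (it >= burn_in && ((it - burn_in) % thin == 0)) {
      mu_sum += mu;
      ve_sum += ve;
      ++n_saved;
    }
  }
  return List::create(_["mu"] = mu_sum / n_saved,
                      _["effects"] = beta_sum / n_saved,
                      _["inclusion_prob"] = incl_sum / n_saved,
                      _["ve"] = ve_sum / n_saved,
                      _["n_saved"] = n_saved);
}
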