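// Compiled kernel for the coordinate-wise slice sampler over the
// psychometric parameters (mu, sigma, lambda_a, lambda_v). Uses R's RNG,
// so runs are reproducible under set.seed(). The R-level
// log_posterior_unnorm() is the independent reference for this density.
#include <Rcpp.h>
using namespace Rcpp;

// unnormalized log posterior: binomial likelihood (no binomial
// coefficients; constant in the parameters) + priors
static double log_post(const double th[4],
                       const NumericVector &x, const NumericVector &c,
                       const NumericVector &n,
                       double mu0, double sd0,          // Normal prior on mu
                       double kshape, double kscale,    // Gamma prior on sigma
                       double ba, double bb) {          // Beta prior on lapses
  const double mu = th[0], sig = th[1], la = th[2], lv = th[3];
  if (!(sig > 0.0) || la < 0.0 || lv < 0.0 || la + lv >= 1.0)
    return R_NegInf;
  double ll = 0.0;
  const double span = 1.0 - la - lv;
  for (int i = 0; i < x.size(); ++i) {
    if (n[i] <= 0.0) continue;
    const double f = 1.0 / (1.0 + std::exp(-(x[i] - mu) / sig));
    const double p = la + span * f;
    ll += c[i] * std::log(p) + (n[i] - c[i]) * std::log1p(-p);
  }
  ll += R::dnorm(mu, mu0, sd0, 1);
  ll += R::dgamma(sig, kshape, kscale, 1);
  ll += R::dbeta(la, ba, bb, 1);
  ll += R::dbeta(lv, ba, bb, 1);
  return ll;
}

// [[Rcpp::export]]
double cpp_log_posterior(NumericVector theta, NumericVector x,
                         NumericVector c, NumericVector n,
                         double mu_mean, double mu_sd,
                         double sigma_shape, double sigma_scale,
                         double lapse_shape1, double lapse_shape2) {
  double th[4] = {theta[0], theta[1], theta[2], theta[3]};
  return log_post(th, x, c, n, mu_mean, mu_sd, sigma_shape, sigma_scale,
                  lapse_shape1, lapse_shape2);
}

// [[Rcpp::export]]
NumericMatrix cpp_slice_sample(NumericVector x, NumericVector c,
                               NumericVector n,
                               double mu_mean, double mu_sd,
                               double sigma_shape, double sigma_scale,
                               double lapse_shape1, double lapse_shape2,
                               int n_samples, int burn_in, int thin,
                               NumericVector init, NumericVector widths,
                               int max_steps = 50) {
  double th[4] = {init[0], init[1], init[2], init[3]};
  double f_cur = log_post(th, x, c, n, mu_mean, mu_sd, sigma_shape,
                          sigma_scale, lapse_shape1, lapse_shape2);
  if (!R_finite(f_cur))
    stop("posterior is not finite at the initial values");
  NumericMatrix out(n_samples, 4);
  const int n_raw = burn_in + thin * n_samples;
  int kept = 0;
  for (int it = 1; it <= n_raw; ++it) {
    for (int j = 0; j < 4; ++j) {
      // stepping-out, then shrinkage (Neal 2003)
      const double x0 = th[j];
      const double y = f_cur + std::log(R::unif_rand());
      double L = x0 - R::unif_rand() * widths[j];
      double R_ = L + widths[j];
      double trial[4] = {th[0], th[1], th[2], th[3]};
      for (int k = 0; k < max_steps; ++k) {
        trial[j] = L;
        if (log_post(trial, x, c, n, mu_mean, mu_sd, sigma_shape,
                     sigma_scale, lapse_shape1, lapse_shape2) <= y) break;
        L -= widths[j];
      }
      for (int k = 0; k < max_steps; ++k) {
        trial[j] = R_;
        if (log_post(trial, x, c, n, mu_mean, mu_sd, sigma_shape,
                     sigma_scale, lapse_shape1, lapse_shape2) <= y) break;
        R_ += widths[j];
      }
      for (;;) {
        const double x1 = L + R::unif_rand() * (R_ - L);
        trial[j] = x1;
        const double f1 = log_post(trial, x, c, n, mu_mean, mu_sd,
                                   sigma_shape, sigma_scale,
                                   lapse_shape1, lapse_shape2);
        if (f1 >= y) { th[j] = x1; f_cur = f1; break; }
        if (x1 < x0) L = x1; else R_ = x1;
      }
    }
    if (it > burn_in && (it - burn_in) % thin == 0) {
      for (int j = 0; j < 4; ++j) out(kept, j) = th[j];
      ++kept;
    }
  }
  colnames(out) = CharacterVector::create("mu", "sigma", "lambda_a", "lambda_v");
  return out;
}
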