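// Compiled kernel for the race-model resampling null: simulates
// antithetic-minimum samples, applies the progressive kill-the-twin
// correction, optionally re-estimates the race bound from bootstrap
// resamples of the unisensory samples, and returns the D* draws. Uses R's
// RNG, so results are reproducible under set.seed(). The R-level
// implementation of the same procedure (race_null_ds) is the reference in
// the tests.
#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// quantile of the piecewise-linear empirical quantile function under the
// (i - 0.5)/n plotting-position convention; lat is sorted finite, n_total
// counts infinite entries too. Beyond finite support -> +Inf; below the
// first position clamps to the minimum.
static double quant_pp(const std::vector<double> &lat, int n_total, double p) {
  const int m = (int)lat.size();
  const double x = p * n_total - 0.5;
  if (x > m - 1.0) return R_PosInf;
  if (x <= 0.0) return lat[0];
  const int i = (int)std::floor(x);
  const double frac = x - i;
  if (i >= m - 1) return lat[m - 1];
  return lat[i] + frac * (lat[i + 1] - lat[i]);
}

// piecewise-linear empirical CDF at t (plotting positions, ties collapsed
// to the largest position); 0 below the smallest latency, flat at the last
// finite position above the largest.
static double cdf_pp(const std::vector<double> &lat, int n_total, double t) {
  const int m = (int)lat.size();
  if (m == 0 || t < lat[0]) return 0.0;
  // last index with lat[k] <= t
  int k = (int)(std::upper_bound(lat.begin(), lat.end(), t) - lat.begin()) - 1;
  const double pos_k = (k + 0.5) / n_total;
  if (lat[k] == t || k == m - 1) return pos_k;
  const double pos_k1 = (k + 1.5) / n_total;
  return pos_k + (t - lat[k]) / (lat[k + 1] - lat[k]) * (pos_k1 - pos_k);
}

// sum over percentiles of the earliest times at which the capped summed
// CDF min(1, Fa(t - dA) + Fv(t - dV)) reaches them; NA if never reached
static double bound_qsum(const std::vector<double> &la, int na,
                         const std::vector<double> &lv, int nv,
                         double dA, double dV,
                         const NumericVector &pct) {
  std::vector<double> grid;
  grid.reserve(la.size() + lv.size());
  for (double v : la) grid.push_back(v + dA);
  for (double v : lv) grid.push_back(v + dV);
  std::sort(grid.begin(), grid.end());
  grid.erase(std::unique(grid.begin(), grid.end()), grid.end());
  const int G = (int)grid.size();
  std::vector<double> B(G);
  for (int i = 0; i < G; ++i) {
    double b = cdf_pp(la, na, grid[i] - dA) + cdf_pp(lv, nv, grid[i] - dV);
    B[i] = b > 1.0 ? 1.0 : b;
  }
  double total = 0.0;
  for (int k = 0; k < pct.size(); ++k) {
    const double p = pct[k];
    int i = 0;
    while (i < G && B[i] < p) ++i;
    if (i == G) return NA_REAL;
    if (i == 0) total += grid[0];
    else total += grid[i - 1] +
      (p - B[i - 1]) * (grid[i] - grid[i - 1]) / (B[i] - B[i - 1]);
  }
  return total;
}

// [[Rcpp::export]]
NumericVector cpp_race_null_ds(NumericVector aud_lat, int aud_n_total,
                               NumericVector vis_lat, int vis_n_total,
                               double dA, double dV, int n_out,
                               NumericVector catch_resp, int n_iter,
                               NumericVector percentiles, bool regen_bound,
                               double bound_sum) {
  std::vector<double> la(aud_lat.begin(), aud_lat.end());
  std::vector<double> lv(vis_lat.begin(), vis_lat.end());
  std::vector<double> guesses(catch_resp.begin(), catch_resp.end());
  std::sort(guesses.begin(), guesses.end());
  const int ma = (int)la.size(), mv = (int)lv.size();

  NumericVector out(n_iter);
  std::vector<double> sim(n_out), boot_a, boot_v, sorted(n_out);
  for (int it = 0; it < n_iter; ++it) {
    // antithetic race minima on the first-stimulus clock
    for (int j = 0; j < n_out; ++j) {
      const double u = R::unif_rand();
      const double qa = quant_pp(la, aud_n_total, u) + dA;
      const double qv = quant_pp(lv, vis_n_total, 1.0 - u) + dV;
      sim[j] = qa < qv ? qa : qv;
    }
    // progressive kill-the-twin: per catch response (ascending) replace
    // the nearest finite latency (tie: the lower one) by +Inf
    for (double g : guesses) {
      int best = -1;
      double bd = R_PosInf, bl = R_PosInf;
      for (int j = 0; j < n_out; ++j) {
        if (!R_finite(sim[j])) continue;
        const double dd = std::fabs(sim[j] - g);
        if (dd < bd || (dd == bd && sim[j] < bl)) {
          bd = dd; bl = sim[j]; best = j;
        }
      }
      if (best < 0) break; // no finite latencies left
      sim[best] = R_PosInf;
    }
    // quantiles of the simulated sample
    sorted = sim;
    std::sort(sorted.begin(), sorted.end());
    double qsum = 0.0;
    bool ok = true;
    for (int k = 0; k < percentiles.size() && ok; ++k) {
      const double x = percentiles[k] * n_out - 0.5;
      if (x <= 0.0) { qsum += sorted[0]; continue; }
      const int i = (int)std::floor(x);
      const double frac = x - i;
      double q;
      if (i >= n_out - 1) q = sorted[n_out - 1];
      else q = sorted[i] + frac * (sorted[i + 1] - sorted[i]);
      if (!R_finite(q)) ok = false; else qsum += q;
    }
    if (!ok) { out[it] = R_NegInf; continue; }

    double bsum;
    if (regen_bound) {
      // with-replacement resamples of the full unisensory multisets
      boot_a.clear(); boot_v.clear();
      for (int j = 0; j < aud_n_total; ++j) {
        const int idx = (int)(R::unif_rand() * aud_n_total);
        if (idx < ma) boot_a.push_back(la[idx]); // idx >= ma draws an Inf entry
      }
      for (int j = 0; j < vis_n_total; ++j) {
        const int idx = (int)(R::unif_rand() * vis_n_total);
        if (idx < mv) boot_v.push_back(lv[idx]);
      }
      if (boot_a.empty() || boot_v.empty()) { out[it] = R_NegInf; continue; }
      std::sort(boot_a.begin(), boot_a.end());
      std::sort(boot_v.begin(), boot_v.end());
      bsum = bound_qsum(boot_a, aud_n_total, boot_v, vis_n_total, dA, dV,
                        percentiles);
      if (!R_finite(bsum)) { out[it] = R_NegInf; continue; }
    } else {
      bsum = bound_sum;
    }
    const double ds = qsum - bsum;
    out[it] = R_finite(ds) ? ds : R_NegInf;
  }
  return out;
}
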