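#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Conditional log-likelihood (and score pieces) of a mixture-thinning
// threshold recursion with Poisson innovations, conditioning on the first
// observation.  Regime 1 applies binomial thinning with probability
// phi1[t], regime 2 negative-binomial thinning (sum of x geometrics with
// success 1/(1+phi2[t])).  The regime of step t is decided by x[t-1] <= r,
// with R = 1 swapping which operator sits below the threshold.
//
// The per-step transition probability is the convolution
//   p_t = sum_m  thin_pmf(m | x_{t-1}, phi) * dpois(x_t - m | lambda),
// accumulated in linear space (all terms lie in [0,1]); log-gamma values
// are table-driven.  Steps with p_t below 1e-300 are floored so degenerate
// parameter corners stay finite during optimization (their score
// contribution is dropped).
//
// Returns: loglik, per-step d log p_t / d phi_t for the active regime
// ("dphi", zero at t = 0 and at floored steps), the total
// d loglik / d lambda, and the regime-1 indicator per step.

static const double P_FLOOR = 1e-300;
static const double LOG_P_FLOOR = std::log(1e-300);

// [[Rcpp::export]]
List mixthin_score_cpp(IntegerVector x, NumericVector phi1,
                       NumericVector phi2, double lambda, double r, int R) {
  const int n = x.size();
  int maxx = 0;
  for (int t = 0; t < n; ++t) maxx = std::max(maxx, x[t]);
  std::vector<double> lgam(2 * maxx + 2);
  for (size_t k = 0; k < lgam.size(); ++k)
    lgam[k] = std::lgamma((double) k);
  const double llam = std::log(lambda);

  NumericVector dphi(n);
  LogicalVector reg1(n);
  double ll = 0.0, dlam = 0.0;

  for (int t = 1; t < n; ++t) {
    const int xp = x[t - 1], xt = x[t];
    const bool below = xp <= r;
    const bool i1 = (R == 0) ? below : !below;
    reg1[t] = i1;
    double p = 0.0, aphi = 0.0, alam = 0.0;

    if (xp == 0) {
      // thinning of 0 is 0: pure Poisson innovation
      const double lp = -lambda + xt * llam - lgam[xt + 1];
      const double w = std::exp(lp);
      p = w;
      alam = w * (xt / lambda - 1.0);
    } else if (i1) {
      const double phi = phi1[t];
      const double lphi = std::log(phi), l1m = std::log1p(-phi);
      const int mmax = std::min(xp, xt);
      const double lch0 = lgam[xp + 1];
      for (int m = 0; m <= mmax; ++m) {
        double lb = lch0 - lgam[m + 1] - lgam[xp - m + 1];
        if (m > 0) lb += m * lphi;
        if (xp - m > 0) lb += (xp - m) * l1m;
        const double lp = -lambda + (xt - m) * llam - lgam[xt - m + 1];
        const double w = std::exp(lb + lp);
        p += w;
        aphi += w * (m / phi - (xp - m) / (1.0 - phi));
        alam += w * ((xt - m) / lambda - 1.0);
      }
    } else {
      const double phi = phi2[t];
      const double lphi = std::log(phi), l1p = std::log1p(phi);
      for (int m = 0; m <= xt; ++m) {
        double lb = lgam[xp + m] - lgam[xp] - lgam[m + 1] -
                    (xp + m) * l1p;
        if (m > 0) lb += m * lphi;
        const double lp = -lambda + (xt - m) * llam - lgam[xt - m + 1];
        const double w = std::exp(lb + lp);
        p += w;
        aphi += w * (m / phi - (xp + m) / (1.0 + phi));
        alam += w * ((xt - m) / lambda - 1.0);
      }
    }

    if (!(p > P_FLOOR) || !R_FINITE(p)) {
      ll += LOG_P_FLOOR;
      dphi[t] = 0.0;
    } else {
      ll += std::log(p);
      dphi[t] = aphi / p;
      dlam += alam / p;
    }
  }
  return List::create(_["loglik"] = ll, _["dphi"] = dphi,
                      _["dlambda"] = dlam, _["reg1"] = reg1);
}

// Value-only variant (cheaper bookkeeping; same floor conventions).
// [[Rcpp::export]]
double mixthin_loglik_cpp(IntegerVector x, NumericVector phi1,
                          NumericVector phi2, double lambda, double r,
                          int R) {
  const int n = x.size();
  int maxx = 0;
  for (int t = 0; t < n; ++t) maxx = std::max(maxx, x[t]);
  std::vector<double> lgam(2 * maxx + 2);
  for (size_t k = 0; k < lgam.size(); ++k)
    lgam[k] = std::lgamma((double) k);
  const double llam = std::log(lambda);
  double ll = 0.0;

  for (int t = 1; t < n; ++t) {
    const int xp = x[t - 1], xt = x[t];
    const bool below = xp <= r;
    const bool i1 = (R == 0) ? below : !below;
    double p = 0.0;
    if (xp == 0) {
      p = std::exp(-lambda + xt * llam - lgam[xt + 1]);
    } else if (i1) {
      const double phi = phi1[t];
      const double lphi = std::log(phi), l1m = std::log1p(-phi);
      const int mmax = std::min(xp, xt);
      const double lch0 = lgam[xp + 1];
      for (int m = 0; m <= mmax; ++m) {
        double lb = lch0 - lgam[m + 1] - lgam[xp - m + 1];
        if (m > 0) lb += m * lphi;
        if (xp - m > 0) lb += (xp - m) * l1m;
        p += std::exp(lb - lambda + (xt - m) * llam - lgam[xt - m + 1]);
      }
    } else {
      const double phi = phi2[t];
      const double lphi = std::log(phi), l1p = std::log1p(phi);
      for (int m = 0; m <= xt; ++m) {
        double lb = lgam[xp + m] - lgam[xp] - lgam[m + 1] -
                    (xp + m) * l1p;
        if (m > 0) lb += m * lphi;
        p += std::exp(lb - lambda + (xt - m) * llam - lgam[xt - m + 1]);
      }
    }
    ll += (p > P_FLOOR && R_FINITE(p)) ? std::log(p) : LOG_P_FLOOR;
  }
  return ll;
}
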