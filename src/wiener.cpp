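// Wiener first-passage-time kernel: density, grouped log-likelihood, and an
// Euler-Maruyama sampler with Brownian-bridge crossing correction.
//
// Parameterisation: drift v, boundary separation a, relative starting point w
// (fraction of a, measured from the lower boundary), non-decision time tau.
// Diffusion coefficient fixed at 1. Upper boundary = correct response under
// accuracy coding.

#include <Rcpp.h>
using namespace Rcpp;

static const double SERIES_ERR = 1e-12;

// Standardised lower-boundary FPT density at scaled time t = u / a^2 for a
// unit-boundary, zero-drift process started at w. Small-time and large-time
// series with truncation bounds chosen so the truncation error is below
// SERIES_ERR; the cheaper representation is used.
static double fpt_std(double t, double w) {
  if (t <= 0.0 || !R_finite(t)) return 0.0;

  // required terms, small-time representation
  double ks;
  if (2.0 * sqrt(2.0 * M_PI * t) * SERIES_ERR < 1.0) {
    ks = 2.0 + sqrt(-2.0 * t * log(2.0 * SERIES_ERR * sqrt(2.0 * M_PI * t)));
    double lb = sqrt(t) + 1.0;
    if (ks < lb) ks = lb;
  } else {
    ks = 2.0;
  }
  // required terms, large-time representation
  double kl;
  if (M_PI * t * SERIES_ERR < 1.0) {
    kl = sqrt(-2.0 * log(M_PI * t * SERIES_ERR) / (M_PI * M_PI * t));
    double lb = 1.0 / (M_PI * sqrt(t));
    if (kl < lb) kl = lb;
  } else {
    kl = 1.0 / (M_PI * sqrt(t));
  }

  double f = 0.0;
  if (ks < kl) {
    int K = (int)ceil(ks);
    for (int k = -((K - 1) / 2); k <= ((K - 1) / 2) + 1; k++) {
      double x = w + 2.0 * k;
      f += x * exp(-x * x / (2.0 * t));
    }
    f /= sqrt(2.0 * M_PI * t * t * t);
  } else {
    int K = (int)ceil(kl);
    for (int k = 1; k <= K; k++) {
      f += k * exp(-k * k * M_PI * M_PI * t / 2.0) * sin(k * M_PI * w);
    }
    f *= M_PI;
  }
  return f > 0.0 ? f : 0.0;
}

// log FPT density at time t for the given boundary (1 = upper, 0 = lower).
static double wiener_logdens(double t, double v, double a, double w,
                             double tau, int upper) {
  double u = t - tau;
  if (u <= 0.0) return R_NegInf;
  if (upper) {  // reflect: upper passage of (v, w) = lower passage of (-v, 1-w)
    v = -v;
    w = 1.0 - w;
  }
  double tstar = u / (a * a);
  double f = fpt_std(tstar, w);
  if (f <= 0.0) return R_NegInf;
  return -v * a * w - v * v * u / 2.0 - 2.0 * log(a) + log(f);
}

// [[Rcpp::export]]
NumericVector wiener_logdens_cpp(NumericVector t, NumericVector v,
                                 NumericVector a, NumericVector w,
                                 NumericVector tau, IntegerVector upper) {
  int n = t.size();
  NumericVector out(n);
  for (int i = 0; i < n; i++) {
    out[i] = wiener_logdens(t[i], v[i], a[i], w[i], tau[i], upper[i]);
  }
  return out;
}

// Sum of per-trial log densities accumulated into groups (e.g. participants or
// participant-condition cells). A single -Inf trial makes its group -Inf.
// [[Rcpp::export]]
NumericVector wiener_loglik_grouped_cpp(NumericVector t, IntegerVector upper,
                                        IntegerVector group, NumericVector v,
                                        NumericVector a, NumericVector w,
                                        NumericVector tau, int ngroups) {
  NumericVector out(ngroups);  // zero-initialised
  int n = t.size();
  for (int i = 0; i < n; i++) {
    int g = group[i];
    if (!R_finite(out[g]) ) continue;
    double ld = wiener_logdens(t[i], v[i], a[i], w[i], tau[i], upper[i]);
    if (ld == R_NegInf) out[g] = R_NegInf; else out[g] += ld;
  }
  return out;
}

// Euler-Maruyama simulation of the diffusion path with optional exact
// Brownian-bridge crossing probabilities between grid points (removes the
// O(sqrt(dt)) first-passage bias of naive discretisation). Returns decision
// times (tau added by the caller-facing R wrapper) and boundaries; a path not
// absorbed by t_max is flagged with boundary = NA.
// [[Rcpp::export]]
List wiener_sample_euler_cpp(int n, double v, double a, double w, double dt,
                             bool bridge, double t_max) {
  NumericVector dt_out(n);
  IntegerVector up_out(n);
  double sdt = sqrt(dt);
  for (int i = 0; i < n; i++) {
    double x = w * a;
    double t = 0.0;
    int hit = NA_INTEGER;
    while (t < t_max) {
      double xn = x + v * dt + sdt * norm_rand();
      t += dt;
      if (xn >= a) { hit = 1; break; }
      if (xn <= 0.0) { hit = 0; break; }
      if (bridge) {
        // exact probability that the bridge from x to xn crossed a boundary;
        // only spend RNG draws when the probability is non-negligible
        double eu = -2.0 * (a - x) * (a - xn) / dt;
        if (eu > -30.0 && unif_rand() < exp(eu)) { hit = 1; break; }
        double el = -2.0 * x * xn / dt;
        if (el > -30.0 && unif_rand() < exp(el)) { hit = 0; break; }
      }
      x = xn;
    }
    // crossing occurred somewhere inside the last step; use its midpoint
    dt_out[i] = t - dt / 2.0;
    up_out[i] = hit;
  }
  return List::create(_["dt"] = dt_out, _["upper"] = up_out);
}
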