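#include <Rcpp.h>
using namespace Rcpp;

// Univariate Kalman filter + RTS smoother for
//   x_t = rho * x_{t-1} + eta_t,  eta_t ~ N(0, q)   [q = sigma_eta^2]
//   y_t = x_t + eps_t,            eps_t ~ N(0, r)   [r = sigma_eps^2]
// with initial state mean m0 and variance p0 (p0 = 0: known x0).
// NA observations skip the update step and propagate the prediction.
// Variances used as divisors are floored at 1e-12; clips are counted.

static const double VAR_FLOOR = 1e-12;

// [[Rcpp::export]]
List kalman_pass_cpp(NumericVector y, double rho, double q, double r,
                     double m0, double p0, bool smooth) {
  const int n = y.size();
  NumericVector pred_m(n), pred_v(n), filt_m(n), filt_v(n);
  double loglik = 0.0;
  int n_obs = 0, n_clip = 0;
  bool degenerate = false;

  double m = m0, p = p0;
  for (int t = 0; t < n; ++t) {
    // prediction
    double pm = rho * m;
    double pv = rho * rho * p + q;
    pred_m[t] = pm;
    pred_v[t] = pv;
    if (NumericVector::is_na(y[t])) {
      m = pm;
      p = pv;
    } else {
      double S = pv + r;
      if (S < VAR_FLOOR) {
        // deterministic prediction: a nonzero innovation is inconsistent
        double resid = y[t] - pm;
        if (std::fabs(resid) > 1e-8) degenerate = true;
        S = VAR_FLOOR;
        ++n_clip;
      }
      double v = y[t] - pm;
      loglik += -0.5 * (std::log(2.0 * M_PI * S) + v * v / S);
      double K = pv / S;
      m = pm + K * v;
      p = (1.0 - K) * pv;
      ++n_obs;
    }
    filt_m[t] = m;
    filt_v[t] = p;
  }

  List out = List::create(
    _["pred_mean"] = pred_m, _["pred_var"] = pred_v,
    _["filt_mean"] = filt_m, _["filt_var"] = filt_v,
    _["loglik"] = loglik, _["n_obs"] = n_obs,
    _["n_clipped"] = n_clip, _["degenerate"] = degenerate);

  if (smooth) {
    NumericVector sm_m = clone(filt_m), sm_v = clone(filt_v);
    for (int t = n - 2; t >= 0; --t) {
      double pv = pred_v[t + 1];
      double C;
      if (pv < VAR_FLOOR) {
        C = 0.0; // deterministic transition: filtered = smoothed
      } else {
        C = filt_v[t] * rho / pv;
      }
      sm_m[t] = filt_m[t] + C * (sm_m[t + 1] - pred_m[t + 1]);
      sm_v[t] = filt_v[t] + C * C * (sm_v[t + 1] - pred_v[t + 1]);
      if (sm_v[t] < 0.0) sm_v[t] = 0.0;
    }
    out["sm_mean"] = sm_m;
    out["sm_var"] = sm_v;
  }
  return out;
}

// Marginal log-likelihood only (fast path for optimisation).
// [[Rcpp::export]]
double kalman_loglik_cpp(NumericVector y, double rho, double q, double r,
                         double m0, double p0) {
  const int n = y.size();
  double loglik = 0.0;
  double m = m0, p = p0;
  for (int t = 0; t < n; ++t) {
    double pm = rho * m;
    double pv = rho * rho * p + q;
    if (NumericVector::is_na(y[t])) {
      m = pm;
      p = pv;
    } else {
      double S = pv + r;
      if (S < VAR_FLOOR) S = VAR_FLOOR;
      double v = y[t] - pm;
      loglik += -0.5 * (std::log(2.0 * M_PI * S) + v * v / S);
      double K = pv / S;
      m = pm + K * v;
      p = (1.0 - K) * pv;
    }
  }
  return loglik;
}
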