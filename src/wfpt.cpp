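#include <Rcpp.h>
using namespace Rcpp;

// Wiener first-passage-time density at the LOWER boundary for a diffusion
// with unit diffusion coefficient, boundary separation a, relative start w
// (start point w*a) and drift v.  Evaluated via the dual series of
// Navarro & Fuss (2009, J Math Psych): the density of the normalized
// process (a = 1, t* = t / a^2, v = 0) is computed with whichever of the
// short-time or long-time expansion needs fewer terms for truncation error
// below `eps`, then rescaled by exp(-v*a*w - v^2 t / 2) / a^2.

static double wfpt_lower_norm(double tt, double w, double eps) {
  // density of normalized process (a=1, v=0) at scaled time tt
  double ks, kl;
  if (M_PI * tt * eps < 1.0) {
    kl = std::sqrt(-2.0 * std::log(M_PI * tt * eps) / (M_PI * M_PI * tt));
    kl = std::max(kl, 1.0 / (M_PI * std::sqrt(tt)));
  } else {
    kl = 1.0 / (M_PI * std::sqrt(tt));
  }
  if (2.0 * std::sqrt(2.0 * M_PI * tt) * eps < 1.0) {
    ks = 2.0 + std::sqrt(-2.0 * tt * std::log(2.0 * std::sqrt(2.0 * M_PI * tt) * eps));
    ks = std::max(ks, std::sqrt(tt) + 1.0);
  } else {
    ks = 2.0;
  }
  double p = 0.0;
  if (ks < kl) {                       // short-time expansion
    int K = (int) std::ceil(ks);
    int lo = -((K - 1) / 2), hi = (K - 1) / 2 + ((K - 1) % 2);
    for (int k = lo; k <= hi; ++k) {
      double u = w + 2.0 * k;
      p += u * std::exp(-u * u / (2.0 * tt));
    }
    p /= std::sqrt(2.0 * M_PI * tt * tt * tt);
  } else {                             // long-time expansion
    int K = (int) std::ceil(kl);
    for (int k = 1; k <= K; ++k) {
      p += k * std::exp(-k * k * M_PI * M_PI * tt / 2.0) * std::sin(k * M_PI * w);
    }
    p *= M_PI;
  }
  return p;
}

static double wfpt_log_lower(double t, double v, double a, double w, double eps) {
  if (t <= 0.0 || a <= 0.0 || w <= 0.0 || w >= 1.0) return R_NegInf;
  double tt = t / (a * a);
  double p = wfpt_lower_norm(tt, w, eps);
  if (p <= 0.0 || !R_finite(p)) return R_NegInf;
  return std::log(p) - v * a * w - v * v * t / 2.0 - 2.0 * std::log(a);
}

//' @noRd
// [[Rcpp::export(name = ".wfpt_lpdf_cpp")]]
NumericVector wfpt_lpdf_cpp(NumericVector t, LogicalVector upper,
                            double a, double t0, double z, NumericVector v,
                            double eps = 1e-9) {
  int n = t.size();
  NumericVector out(n);
  bool scalar_v = (v.size() == 1);
  for (int i = 0; i < n; ++i) {
    double vi = scalar_v ? v[0] : v[i];
    double td = t[i] - t0;
    if (td <= 0.0) { out[i] = R_NegInf; continue; }
    if (upper[i]) {
      out[i] = wfpt_log_lower(td, -vi, a, 1.0 - z, eps);  // reflection
    } else {
      out[i] = wfpt_log_lower(td, vi, a, z, eps);
    }
  }
  return out;
}

// probability of absorption at the UPPER boundary,
// P = (exp(-2*a*z*v) - 1) / (exp(-2*a*v) - 1), continuous limit z at v -> 0
//' @noRd
// [[Rcpp::export(name = ".prob_upper_cpp")]]
NumericVector prob_upper_cpp(double a, double z, NumericVector v) {
  int n = v.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double av = a * v[i];
    if (std::fabs(av) < 1e-8) {
      out[i] = z * (1.0 + av * (1.0 - z));      // second-order expansion
    } else if (av > 350.0) {
      out[i] = 1.0 - std::exp(-2.0 * av * z) / (1.0 - std::exp(-2.0 * av));
      if (out[i] > 1.0) out[i] = 1.0;
    } else if (av < -350.0) {
      out[i] = std::exp(2.0 * av * (1.0 - z));  // -> 0
    } else {
      out[i] = std::expm1(-2.0 * av * z) / std::expm1(-2.0 * av);
    }
    if (out[i] < 0.0) out[i] = 0.0;
    if (out[i] > 1.0) out[i] = 1.0;
  }
  return out;
}

// pointwise log likelihood for one participant: WFPT for single-response
// trials, absorption probability only for preference-switch trials
//' @noRd
// [[Rcpp::export(name = ".ddm_pointwise_cpp")]]
NumericVector ddm_pointwise_cpp(NumericVector rt, LogicalVector upper,
                                LogicalVector is_switch,
                                double a, double t0, double z,
                                NumericVector v, double eps = 1e-9) {
  int n = rt.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double vi = (v.size() == 1) ? v[0] : v[i];
    if (is_switch[i]) {
      NumericVector pv = prob_upper_cpp(a, z, NumericVector::create(vi));
      double p = upper[i] ? pv[0] : 1.0 - pv[0];
      out[i] = (p > 0.0) ? std::log(p) : R_NegInf;
    } else {
      double td = rt[i] - t0;
      if (td <= 0.0) { out[i] = R_NegInf; continue; }
      out[i] = upper[i] ? wfpt_log_lower(td, -vi, a, 1.0 - z, eps)
                        : wfpt_log_lower(td, vi, a, z, eps);
    }
  }
  return out;
}

// Euler-Maruyama forward simulation of the diffusion; independent oracle
// for the series density and the default sampler.  Uses R's RNG stream.
//' @noRd
// [[Rcpp::export(name = ".sim_ddm_euler_cpp")]]
List sim_ddm_euler_cpp(int n, double v, double a, double z,
                       double dt = 1e-3, double tmax = 60.0) {
  NumericVector dtv(n);
  IntegerVector up(n);
  double sdt = std::sqrt(dt);
  RNGScope scope;
  for (int i = 0; i < n; ++i) {
    double x = z * a, t = 0.0;
    int hit = NA_INTEGER;
    while (t < tmax) {
      x += v * dt + sdt * norm_rand();
      t += dt;
      if (x >= a) { hit = 1; break; }
      if (x <= 0.0) { hit = 0; break; }
    }
    dtv[i] = t;
    up[i] = hit;
  }
  return List::create(_["dt"] = dtv, _["upper"] = up);
}
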