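#include <Rcpp.h>
using namespace Rcpp;

// Euler-Maruyama integrators for the two normal-form systems and the
// step-current protocol emulator.  Noise is drawn through R's RNG
// (norm_rand), so paths are bit-reproducible under set.seed() on the R side.
//
// Pulse kicks are instantaneous additive state increments applied at known
// sample indices (1-based, referring to the output grid): the state at a
// pulse index already contains the kick.

// [[Rcpp::export]]
List sn_path_cpp(double y0, double V0, double eps, double rho, double sigma1,
                 double kick, IntegerVector pulse_idx, double dt, int n_steps,
                 double escape_bound) {
  NumericVector V(n_steps + 1);
  V[0] = V0;
  std::vector<bool> is_pulse(n_steps + 2, false);
  for (int i = 0; i < pulse_idx.size(); ++i) {
    int p = pulse_idx[i];
    if (p >= 1 && p <= n_steps + 1) is_pulse[p] = true;
  }
  double sdt = std::sqrt(dt);
  int escape = NA_INTEGER, bad = NA_INTEGER;
  int len = n_steps + 1;
  for (int k = 0; k < n_steps; ++k) {
    double y = y0 - eps * dt * k;
    double v = V[k] + (-y + rho * V[k] * V[k]) * dt;
    if (sigma1 > 0.0) v += sigma1 * sdt * norm_rand();
    if (is_pulse[k + 2]) v += kick;  // sample k+1 has 1-based index k+2
    V[k + 1] = v;
    if (!std::isfinite(v)) { bad = k + 2; len = k + 2; break; }
    double ynext = y0 - eps * dt * (k + 1);
    double vplus = std::sqrt(std::max(ynext, 0.0) / rho);
    if (v > vplus + 1.0 || std::fabs(v) > escape_bound) {
      escape = k + 2;  // 1-based index of the escaping sample
      len = k + 2;
      break;
    }
  }
  if (len < n_steps + 1) V = NumericVector(V.begin(), V.begin() + len);
  return List::create(_["V"] = V, _["escape_idx"] = escape,
                      _["bad_idx"] = bad);
}

// [[Rcpp::export]]
List hopf_path_cpp(double y0, double V1_0, double V2_0, double eps,
                   double sigma1, double sigma2, double kick,
                   IntegerVector pulse_idx, double dt, int n_steps,
                   double escape_bound) {
  NumericVector V1(n_steps + 1), V2(n_steps + 1);
  V1[0] = V1_0;
  V2[0] = V2_0;
  std::vector<bool> is_pulse(n_steps + 2, false);
  for (int i = 0; i < pulse_idx.size(); ++i) {
    int p = pulse_idx[i];
    if (p >= 1 && p <= n_steps + 1) is_pulse[p] = true;
  }
  double sdt = std::sqrt(dt);
  int escape = NA_INTEGER, bad = NA_INTEGER;
  int len = n_steps + 1;
  for (int k = 0; k < n_steps; ++k) {
    double y = y0 + eps * dt * k;  // drifts upward toward y_c = 0
    double r2 = V1[k] * V1[k] + V2[k] * V2[k];
    double v1 = V1[k] + (y * V1[k] - V2[k] + V1[k] * r2) * dt;
    double v2 = V2[k] + (V1[k] + y * V2[k] + V2[k] * r2) * dt;
    if (sigma1 > 0.0) v1 += sigma1 * sdt * norm_rand();
    if (sigma2 > 0.0) v2 += sigma2 * sdt * norm_rand();
    if (is_pulse[k + 2]) { v1 += kick; v2 += kick; }
    V1[k + 1] = v1;
    V2[k + 1] = v2;
    if (!std::isfinite(v1) || !std::isfinite(v2)) { bad = k + 2; len = k + 2; break; }
    double ynext = y0 + eps * dt * (k + 1);
    double rad = std::sqrt(v1 * v1 + v2 * v2);
    double basin = std::max(2.0 * std::sqrt(std::max(-ynext, 0.0)), 0.5);
    if (rad > basin || rad > escape_bound) {
      escape = k + 2;
      len = k + 2;
      break;
    }
  }
  if (len < n_steps + 1) {
    V1 = NumericVector(V1.begin(), V1.begin() + len);
    V2 = NumericVector(V2.begin(), V2.begin() + len);
  }
  return List::create(_["V1"] = V1, _["V2"] = V2, _["escape_idx"] = escape,
                      _["bad_idx"] = bad);
}

// Saddle-node dynamics under a per-step-constant control parameter
// (staircase), sampled on a uniform grid.  y_steps[s] applies to samples
// belonging to protocol step s.
//
// The subthreshold current-voltage relation is parabolic (the fold normal
// form) only within v_par of the fold; below that the emulated membrane
// reverts to a constant passive conductance, i.e. the restoring term
// continues linearly with the slope it has at V = -v_par.  With
// v_par = +Inf this reduces to the pure normal form.  Returns the raw
// state path and the path detrended by the stable branch of the composite
// I-V curve.
static inline double sn_drift(double V, double y, double rho, double v_par) {
  if (V >= -v_par) return -y + rho * V * V;
  return -y + rho * (2.0 * v_par * (-V) - v_par * v_par);
}

static inline double sn_branch(double y, double rho, double v_par) {
  // stable equilibrium of the composite I-V curve (y >= 0 clamped to 0)
  double yy = std::max(y, 0.0);
  double y_par = rho * v_par * v_par;
  if (yy <= y_par) return -std::sqrt(yy / rho);
  return -(yy / rho + v_par * v_par) / (2.0 * v_par);
}

// [[Rcpp::export]]
List staircase_sn_cpp(NumericVector y_steps, int samples_per_step, double V0,
                      double rho, double sigma1, double kick,
                      IntegerVector pulse_idx, double dt,
                      double escape_bound, double v_par) {
  int n_total = y_steps.size() * samples_per_step;
  NumericVector V(n_total), Vd(n_total);
  std::vector<bool> is_pulse(n_total + 1, false);
  for (int i = 0; i < pulse_idx.size(); ++i) {
    int p = pulse_idx[i];
    if (p >= 1 && p <= n_total) is_pulse[p] = true;
  }
  double sdt = std::sqrt(dt);
  V[0] = V0;
  Vd[0] = V0 - sn_branch(y_steps[0], rho, v_par);
  int escape = NA_INTEGER, bad = NA_INTEGER;
  int len = n_total;
  for (int k = 0; k < n_total - 1; ++k) {
    double y = y_steps[k / samples_per_step];
    double v = V[k] + sn_drift(V[k], y, rho, v_par) * dt;
    if (sigma1 > 0.0) v += sigma1 * sdt * norm_rand();
    if (is_pulse[k + 2]) v += kick;  // sample k+1 is 1-based index k+2
    V[k + 1] = v;
    double ynext = y_steps[(k + 1) / samples_per_step];
    Vd[k + 1] = v - sn_branch(ynext, rho, v_par);
    if (!std::isfinite(v)) { bad = k + 2; len = k + 2; break; }
    double vplus = std::sqrt(std::max(ynext, 0.0) / rho);
    if (v > vplus + 1.0 || std::fabs(v) > escape_bound) {
      escape = k + 2;
      len = k + 2;
      break;
    }
  }
  if (len < n_total) {
    V = NumericVector(V.begin(), V.begin() + len);
    Vd = NumericVector(Vd.begin(), Vd.begin() + len);
  }
  return List::create(_["V"] = V, _["Vd"] = Vd, _["escape_idx"] = escape,
                      _["bad_idx"] = bad);
}

// Hopf dynamics under a per-step-constant control parameter.  The
// observable is V1 (the equilibrium is the origin, so no detrending).
// [[Rcpp::export]]
List staircase_hopf_cpp(NumericVector y_steps, int samples_per_step,
                        double V1_0, double V2_0, double sigma1,
                        double sigma2, double kick, IntegerVector pulse_idx,
                        double dt, double escape_bound) {
  int n_total = y_steps.size() * samples_per_step;
  NumericVector V1(n_total), V2(n_total);
  std::vector<bool> is_pulse(n_total + 1, false);
  for (int i = 0; i < pulse_idx.size(); ++i) {
    int p = pulse_idx[i];
    if (p >= 1 && p <= n_total) is_pulse[p] = true;
  }
  double sdt = std::sqrt(dt);
  V1[0] = V1_0;
  V2[0] = V2_0;
  int escape = NA_INTEGER, bad = NA_INTEGER;
  int len = n_total;
  for (int k = 0; k < n_total - 1; ++k) {
    double y = y_steps[k / samples_per_step];
    double r2 = V1[k] * V1[k] + V2[k] * V2[k];
    double v1 = V1[k] + (y * V1[k] - V2[k] + V1[k] * r2) * dt;
    double v2 = V2[k] + (V1[k] + y * V2[k] + V2[k] * r2) * dt;
    if (sigma1 > 0.0) v1 += sigma1 * sdt * norm_rand();
    if (sigma2 > 0.0) v2 += sigma2 * sdt * norm_rand();
    if (is_pulse[k + 2]) { v1 += kick; v2 += kick; }
    V1[k + 1] = v1;
    V2[k + 1] = v2;
    if (!std::isfinite(v1) || !std::isfinite(v2)) { bad = k + 2; len = k + 2; break; }
    double ynext = y_steps[(k + 1) / samples_per_step];
    double rad = std::sqrt(v1 * v1 + v2 * v2);
    double basin = std::max(2.0 * std::sqrt(std::max(-ynext, 0.0)), 0.5);
    if (rad > basin || rad > escape_bound) {
      escape = k + 2;
      len = k + 2;
      break;
    }
  }
  if (len < n_total) {
    V1 = NumericVector(V1.begin(), V1.begin() + len);
    V2 = NumericVector(V2.begin(), V2.begin() + len);
  }
  return List::create(_["V1"] = V1, _["V2"] = V2, _["escape_idx"] = escape,
                      _["bad_idx"] = bad);
}
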