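#include <Rcpp.h>
using namespace Rcpp;

// Logistic activation used by all units.
static inline double sigm(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// Euler integration of the full circuit.
//
// The engine covers all module configurations:
//   * plain BCM          : mpm_on = true,  mpm_reset = false, sam_on = false
//   * MPM (periodic)     : mpm_on = true,  mpm_reset = true,  sam_on = false
//   * SAM only           : mpm_on = false, sam_on = true
//   * coupled SAM + MPM  : both on (alpha >= 0)
//
// All derivatives are evaluated at the current state and the units are
// advanced together (synchronous update). Time stamp of step j (1-based) is
// j * dt; a stimulus with onset o ms is "on" during the step that starts at o,
// i.e. step o/dt + 1.
//
// stim[j-1] = 1 marks stimulus steps; the shared input I is advanced by
// (dt/tau) * s * K * (y_s - y0) except while the first stimulus pulse is on
// (steps <= first_pulse_end, 1-based), where the gain is frozen at zero.
//
// The MPM reset pulse (amplitude Ip inside the sigmoid arguments) is active
// for reset_steps steps beginning the step after a threshold crossing of y_p.
//
// Per-step noise draws use R's RNG so that set.seed() in R controls
// reproducibility. sigma_step is the per-step SD (already discretized by the
// caller); sigma_step = 0 draws nothing.
//
// [[Rcpp::export]]
List cpp_run_circuit(List par,
                     double I0, double K, double alpha,
                     IntegerVector stim, int first_pulse_end,
                     int n_steps, double sigma_step,
                     bool sam_on, bool mpm_on, bool mpm_reset,
                     bool trace) {
  const double tau = par["tau"], dt = par["dt"];
  const double wuI = par["w_uI"], wvI = par["w_vI"];
  const double wuv = par["w_uv"], wvu = par["w_vu"];
  const double wyu = par["w_yu"], wyv = par["w_yv"];
  const double y0 = par["y0"], Ip = par["I_p"], Is = par["I_s"];
  const double u_init = par["u_init"], v_init = par["v_init"],
               y_init = par["y_init"];
  const int reset_steps = par["reset_steps"];
  const double r = dt / tau;

  double us = u_init, vs = v_init, ys = y_init;        // SAM units
  double up = u_init, vp = v_init, yp = y_init;        // MPM units
  double I = I0;

  int reset = 0;
  double yp_prev = yp, ys_prev = ys;
  const bool noisy = sigma_step > 0.0;

  std::vector<int> prod_steps;
  std::vector<int> sam_cross_steps;

  NumericMatrix tr;
  if (trace) tr = NumericMatrix(n_steps, 8); // us vs ys up vp yp I dI

  RNGScope scope;

  bool diverged = false;
  for (int j = 1; j <= n_steps; ++j) {
    const int sj = (j - 1 < stim.size()) ? stim[j - 1] : 0;
    const double dI = (mpm_on && sam_on) ? alpha * (yp - ys) : 0.0;
    const double Keff = (sam_on && j > first_pulse_end) ? K : 0.0;

    double e1 = 0, e2 = 0, e3 = 0, e4 = 0, e5 = 0, e6 = 0;
    if (noisy) {
      if (sam_on) {
        e1 = norm_rand() * sigma_step;
        e2 = norm_rand() * sigma_step;
        e3 = norm_rand() * sigma_step;
      }
      if (mpm_on) {
        e4 = norm_rand() * sigma_step;
        e5 = norm_rand() * sigma_step;
        e6 = norm_rand() * sigma_step;
      }
    }

    double us_n = us, vs_n = vs, ys_n = ys;
    if (sam_on) {
      us_n = us + r * (-us + sigm(wuI * I - wuv * vs + e1 - sj * Is));
      vs_n = vs + r * (-vs + sigm(wvI * I - wvu * us + e2 + sj * Is));
      ys_n = ys + r * (-ys + wyu * us - wyv * vs + e3);
    }
    double up_n = up, vp_n = vp, yp_n = yp;
    if (mpm_on) {
      const double drive = I + dI;
      const double pulse = (reset > 0) ? Ip : 0.0;
      up_n = up + r * (-up + sigm(wuI * drive - wuv * vp + e4 - pulse));
      vp_n = vp + r * (-vp + sigm(wvI * drive - wvu * up + e5 + pulse));
      yp_n = yp + r * (-yp + wyu * up - wyv * vp + e6);
    }
    double I_n = I;
    if (sam_on) I_n = I + r * sj * Keff * (ys - y0);

    us = us_n; vs = vs_n; ys = ys_n;
    up = up_n; vp = vp_n; yp = yp_n;
    I = I_n;

    if (!(std::isfinite(us) && std::isfinite(vs) && std::isfinite(ys) &&
          std::isfinite(up) && std::isfinite(vp) && std::isfinite(yp) &&
          std::isfinite(I))) {
      diverged = true;
      break;
    }

    if (reset > 0) --reset;

    if (mpm_on && yp >= y0 && yp_prev < y0) {
      prod_steps.push_back(j);
      if (mpm_reset) reset = reset_steps;
    }
    if (sam_on && ys >= y0 && ys_prev < y0) sam_cross_steps.push_back(j);

    yp_prev = yp;
    ys_prev = ys;

    if (trace) {
      tr(j - 1, 0) = us; tr(j - 1, 1) = vs; tr(j - 1, 2) = ys;
      tr(j - 1, 3) = up; tr(j - 1, 4) = vp; tr(j - 1, 5) = yp;
      tr(j - 1, 6) = I;  tr(j - 1, 7) = dI;
    }
  }

  List out = List::create(
    _["prod_steps"] = wrap(prod_steps),
    _["sam_cross_steps"] = wrap(sam_cross_steps),
    _["I_final"] = I,
    _["diverged"] = diverged);
  if (trace) out["trace"] = tr;
  return out;
}
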