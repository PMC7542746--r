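#include <Rcpp.h>
using namespace Rcpp;

// Fixed-step (Heun / explicit trapezoidal) integration of the adaptive
// exponential integrate-and-fire membrane equation under a rectangular
// current step.
//
// Units: pF, nS, mV, pA, ms (pA/pF == mV/ms, so no conversion constants).
//
// Spike handling: once the trajectory crosses a registration trigger
// (min(v_cut, V_T + 8 Delta_T); beyond it the exponential blow-up to the
// recorded peak takes microseconds), the crossing time is located by linear
// interpolation within the step and registered as the spike time. The
// sample at the crossing is recorded at v_cut (the stored trace peaks at
// the cutoff), the membrane is reset, the adaptation current incremented by
// b, and the refractory period ends at the continuous time
// spike + t_ref, with a partial step resuming integration. Continuous-time
// events keep spike times second-order accurate in dt instead of
// accumulating one-sample biases per interspike interval.
//
// The exponential term is clamped at exp(30) to avoid overflow and dropped
// below exp(-9) (< 1e-3 pA for physiological g_L * Delta_T). Membrane noise
// is an additive Gaussian increment scaled so that noise_sd is the
// stationary SD (mV) of the free membrane fluctuation; increments are drawn
// by Box-Muller from R's uniform stream, so set.seed() makes traces
// reproducible.

static inline double spike_fn(double vm, double v_t, double delta_t, double gdt) {
  const double ex = (vm - v_t) / delta_t;
  if (ex > 30.0) return gdt * 1.0686e13;
  if (ex < -9.0) return 0.0;
  return gdt * std::exp(ex);
}

static inline double gauss_pair(bool &have, double &spare) {
  if (have) { have = false; return spare; }
  double u1 = R::unif_rand(), u2 = R::unif_rand();
  if (u1 <= 0) u1 = DBL_MIN;
  double r = std::sqrt(-2.0 * std::log(u1));
  double th = 2.0 * M_PI * u2;
  spare = r * std::sin(th);
  have = true;
  return r * std::cos(th);
}

// [[Rcpp::export]]
List adex_step_cpp(double c_m, double g_l, double e_l, double delta_t,
                   double v_t, double v_reset, double v_cut, double t_ref,
                   double a, double b, double tau_w, double noise_sd,
                   int n, double dt, double i_base, double i_step,
                   int onset_idx, int offset_idx) {
  NumericVector v(n);
  std::vector<double> spikes;
  const double inv_c = 1.0 / c_m;
  const double inv_tw = 1.0 / tau_w;
  const double tau_m = c_m / g_l;
  const double sigma_step = noise_sd * std::sqrt(2.0 * dt / tau_m);
  const bool noisy = noise_sd > 0.0;
  const double gdt = g_l * delta_t;
  const double v_trig = std::min(v_cut, v_t + 8.0 * delta_t);
  bool have_spare = false;
  double spare = 0.0;

  double vm = e_l;
  double w = 0.0;
  double ref_end = -1.0;  // continuous time (ms) at which refractoriness ends

  v[0] = vm;
  for (int i = 1; i < n; ++i) {
    const double t_now = i * dt;
    const double I = i_base + ((i >= onset_idx && i < offset_idx) ? i_step : 0.0);
    if (t_now < ref_end) {
      w += dt * (a * (v_reset - e_l) - w) * inv_tw;
      vm = v_reset;
      v[i] = vm;
      continue;
    }
    // step size: full dt, or the partial remainder when leaving refractoriness
    double h = dt;
    if (t_now - dt < ref_end) {
      h = t_now - ref_end;
      vm = v_reset;
      if (h <= 0) { v[i] = vm; continue; }
    }
    const double v0 = vm;
    const double k1v = (-g_l * (vm - e_l) + spike_fn(vm, v_t, delta_t, gdt) - w + I) * inv_c;
    const double k1w = (a * (vm - e_l) - w) * inv_tw;
    const double vp = vm + h * k1v;
    const double wp = w + h * k1w;
    double k2v, k2w;
    if (vp >= v_trig) {
      k2v = k1v; k2w = k1w;  // predictor crossed: the spike fires this step
    } else {
      k2v = (-g_l * (vp - e_l) + spike_fn(vp, v_t, delta_t, gdt) - wp + I) * inv_c;
      k2w = (a * (vp - e_l) - wp) * inv_tw;
    }
    vm += 0.5 * h * (k1v + k2v);
    w += 0.5 * h * (k1w + k2w);
    if (noisy) vm += sigma_step * std::sqrt(h / dt) * gauss_pair(have_spare, spare);
    if (vm >= v_trig) {
      const double theta = (vm > v0) ? (v_trig - v0) / (vm - v0) : 1.0;
      const double t_spike = t_now - h + theta * h;
      spikes.push_back(t_spike);
      v[i] = v_cut;
      vm = v_reset;
      w += b;
      ref_end = t_spike + t_ref;
    } else {
      v[i] = vm;
    }
  }
  return List::create(_["voltage"] = v,
                      _["spike_times_ms"] = NumericVector(spikes.begin(), spikes.end()));
}

// Indices (1-based) at which v crosses `level` upward: v[i-1] < level <= v[i].
// [[Rcpp::export]]
IntegerVector upward_crossings_cpp(NumericVector v, double level) {
  std::vector<int> idx;
  const int n = v.size();
  for (int i = 1; i < n; ++i) {
    if (v[i] >= level && v[i - 1] < level) idx.push_back(i + 1);
  }
  return IntegerVector(idx.begin(), idx.end());
}
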