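#include <Rcpp.h>
using namespace Rcpp;

// Forward-Euler integration of the Izhikevich membrane equations under a
// zero-order-hold input sampled at the sensor rate.  Each input sample is
// held constant and integrated with sub-steps of length dt_ms; the remainder
// of the sample interval is absorbed in the last sub-step.  Times are in ms,
// potentials in mV (canonical Izhikevich convention).
//
// dv/dt = A v^2 + B v + C - u + I * rc
// du/dt = a (b v - u)
// v >= v_th: spike, v <- c_reset, u <- u + d
//
// [[Rcpp::export]]
List izh_integrate_cpp(NumericVector I, double sample_dt_ms, double dt_ms,
                       double A, double B, double C, double rc,
                       double a, double b, double c_reset, double d,
                       double v_th, double v0, double u0,
                       bool record_v = false) {
  const int n = I.size();
  const int n_sub = (int)std::ceil(sample_dt_ms / dt_ms - 1e-12);
  const double dt_last = sample_dt_ms - (n_sub - 1) * dt_ms;

  std::vector<double> spikes;
  std::vector<double> vtrace;
  if (record_v) vtrace.reserve((size_t)n * n_sub);

  double v = v0, u = u0, t = 0.0;
  for (int i = 0; i < n; ++i) {
    const double Ii = I[i] * rc;
    for (int s = 0; s < n_sub; ++s) {
      const double h = (s == n_sub - 1) ? dt_last : dt_ms;
      const double dv = A * v * v + B * v + C - u + Ii;
      const double du = a * (b * v - u);
      v += h * dv;
      u += h * du;
      t += h;
      if (!std::isfinite(v) || !std::isfinite(u))
        stop("Izhikevich state diverged (non-finite) at t = %f ms (sample %d, sub-step %d)",
             t, i + 1, s + 1);
      if (v >= v_th) {
        spikes.push_back(t);
        v = c_reset;
        u += d;
      }
      if (record_v) vtrace.push_back(v);
    }
  }

  List out = List::create(_["spike_times_ms"] = wrap(spikes),
                          _["v_final"] = v, _["u_final"] = u);
  if (record_v) out["v_trace"] = wrap(vtrace);
  return out;
}
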