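#include <Rcpp.h>
using namespace Rcpp;

// 21-node myelinated-axon model with active nodes of Ranvier.
//
// Each node carries fast sodium, persistent sodium, slow potassium and leak
// currents with MRG-style kinetics (36 C); internodes are treated as
// perfectly insulating myelin, so adjacent nodes couple only through the
// intracellular axial resistance of one internode.  The extracellular
// potential enters through the standard activating-function term
// G * lap(Ve).  The membrane equation is advanced with a backward-Euler
// step (conductances frozen within the step) solved by the Thomas
// algorithm; gating variables use exponential-Euler updates.
//
// Units: mV, ms, mS/cm^2, uF/cm^2, uA/cm^2.

namespace {

struct Gates { double m, h, p, s; };

inline double safe_exp_frac(double num, double den) {
  // num / (1 - exp(-num/den-ish)) handled by caller; helper not needed
  return num / den;
}

inline double alpha_m(double V) {
  double x = V + 20.4;
  double e = 1.0 - std::exp(-x / 10.3);
  if (std::fabs(e) < 1e-9) return 6.57 * 10.3;
  return 6.57 * x / e;
}
inline double beta_m(double V) {
  double x = -(V + 25.7);
  double e = 1.0 - std::exp(-x / 9.16);
  if (std::fabs(e) < 1e-9) return 0.304 * 9.16;
  return 0.304 * x / e;
}
inline double alpha_h(double V) {
  double x = -(V + 114.0);
  double e = 1.0 - std::exp(-x / 11.0);
  if (std::fabs(e) < 1e-9) return 0.34 * 11.0;
  return 0.34 * x / e;
}
inline double beta_h(double V) {
  return 12.6 / (1.0 + std::exp(-(V + 31.8) / 13.4));
}
inline double alpha_p(double V) {
  double x = V + 27.0;
  double e = 1.0 - std::exp(-x / 10.2);
  if (std::fabs(e) < 1e-9) return 0.0353 * 10.2;
  return 0.0353 * x / e;
}
inline double beta_p(double V) {
  double x = -(V + 34.0);
  double e = 1.0 - std::exp(-x / 10.0);
  if (std::fabs(e) < 1e-9) return 0.000883 * 10.0;
  return 0.000883 * x / e;
}
inline double alpha_s(double V) {
  return 0.3 / (1.0 + std::exp(-(V + 53.0) / 5.0));
}
inline double beta_s(double V) {
  return 0.03 / (1.0 + std::exp(-(V + 90.0) / 1.0));
}

struct AxonParams {
  double g_naf, g_nap, g_ks, g_l;      // mS/cm^2
  double e_na, e_k, e_l;               // mV
  double c_m;                          // uF/cm^2
  double v_rest;                       // mV
  double G;                            // internodal coupling, mS/cm^2 (per node area)
  int n_nodes;
};

inline void gate_step(Gates &g, double V, double dt) {
  auto upd = [dt](double x, double a, double b) {
    double tau = 1.0 / (a + b), inf = a * tau;
    return inf + (x - inf) * std::exp(-dt / tau);
  };
  g.m = upd(g.m, alpha_m(V), beta_m(V));
  g.h = upd(g.h, alpha_h(V), beta_h(V));
  g.p = upd(g.p, alpha_p(V), beta_p(V));
  g.s = upd(g.s, alpha_s(V), beta_s(V));
}

// One backward-Euler step of length dt with extracellular profile ve (mV).
// Tridiagonal system solved in place via Thomas algorithm.
void cable_step(std::vector<double> &V, std::vector<Gates> &gates,
                const double *ve, double dt, const AxonParams &P,
                std::vector<double> &a, std::vector<double> &b,
                std::vector<double> &c, std::vector<double> &r) {
  const int n = P.n_nodes;
  for (int i = 0; i < n; ++i) {
    gate_step(gates[i], V[i], dt);
    const Gates &g = gates[i];
    double gna = P.g_naf * g.m * g.m * g.m * g.h;
    double gnp = P.g_nap * g.p * g.p * g.p;
    double gks = P.g_ks * g.s;
    double gsum = gna + gnp + gks + P.g_l;
    double esum = gna * P.e_na + gnp * P.e_na + gks * P.e_k + P.g_l * P.e_l;
    double lap_ve;
    if (i == 0)          lap_ve = ve[1] - ve[0];
    else if (i == n - 1) lap_ve = ve[n - 2] - ve[n - 1];
    else                 lap_ve = ve[i - 1] - 2.0 * ve[i] + ve[i + 1];
    double ncoup = (i == 0 || i == n - 1) ? 1.0 : 2.0;
    double diag = P.c_m / dt + gsum + ncoup * P.G;
    a[i] = (i == 0) ? 0.0 : -P.G;
    b[i] = diag;
    c[i] = (i == n - 1) ? 0.0 : -P.G;
    r[i] = P.c_m / dt * V[i] + esum + P.G * lap_ve;
  }
  // Thomas solve
  for (int i = 1; i < n; ++i) {
    double w = a[i] / b[i - 1];
    b[i] -= w * c[i - 1];
    r[i] -= w * r[i - 1];
  }
  V[n - 1] = r[n - 1] / b[n - 1];
  for (int i = n - 2; i >= 0; --i)
    V[i] = (r[i] - c[i] * V[i + 1]) / b[i];
}

AxonParams default_params(double fiber_d_um, int n_nodes) {
  AxonParams P;
  P.g_naf = 3000.0; P.g_nap = 10.0; P.g_ks = 80.0; P.g_l = 7.0;
  P.e_na = 50.0; P.e_k = -90.0; P.e_l = -90.0;
  P.c_m = 2.0; P.v_rest = -80.0; P.n_nodes = n_nodes;
  // Axial coupling: intracellular resistivity 70 Ohm cm, axon diameter
  // 0.7 D, internodal length 100 D, nodal area pi * (D/3) * 1 um.
  double D = fiber_d_um;
  double d_axon_cm = 0.7 * D * 1e-4;
  double L_cm = 100.0 * D * 1e-4;
  double area_axial = M_PI * d_axon_cm * d_axon_cm / 4.0;   // cm^2
  double Ga_S = area_axial / (70.0 * L_cm);                 // S
  double node_area = M_PI * (D / 3.0 * 1e-4) * (1.0 * 1e-4); // cm^2
  P.G = Ga_S * 1000.0 / node_area;                          // mS/cm^2
  return P;
}

// Simulate response to a cathodic-first biphasic balanced square pulse.
// ve_unit: extracellular potential at each node per +1 uA source current (mV).
// Returns max membrane depolarisation (mV above rest) at the last node.
double run_once(const std::vector<double> &ve_unit, double amp_uA,
                double pulse_ms, double dt_pulse, double dt_post,
                double horizon_ms, const AxonParams &P, bool *diverged) {
  const int n = P.n_nodes;
  std::vector<double> V(n, P.v_rest);
  std::vector<Gates> gates(n);
  for (int i = 0; i < n; ++i) {
    double v = P.v_rest;
    gates[i].m = alpha_m(v) / (alpha_m(v) + beta_m(v));
    gates[i].h = alpha_h(v) / (alpha_h(v) + beta_h(v));
    gates[i].p = alpha_p(v) / (alpha_p(v) + beta_p(v));
    gates[i].s = alpha_s(v) / (alpha_s(v) + beta_s(v));
  }
  std::vector<double> ta(n), tb(n), tc(n), tr(n), ve(n), ve0(n, 0.0);
  // settle to the model's own resting state before the pulse
  for (int k = 0; k < 400; ++k)
    cable_step(V, gates, ve0.data(), 0.01, P, ta, tb, tc, tr);
  double v_rest_eff = V[n - 1];

  double vmax_last = -1e9;
  double t = 0.0;
  *diverged = false;
  while (t < horizon_ms) {
    double dt, scale;
    if (t < pulse_ms) { dt = dt_pulse; scale = -amp_uA; }        // cathodic
    else if (t < 2.0 * pulse_ms) { dt = dt_pulse; scale = amp_uA; } // anodic
    else { dt = dt_post; scale = 0.0; }
    for (int i = 0; i < n; ++i) ve[i] = scale * ve_unit[i];
    cable_step(V, gates, ve.data(), dt, P, ta, tb, tc, tr);
    t += dt;
    if (!std::isfinite(V[0]) || !std::isfinite(V[n - 1])) { *diverged = true; return NA_REAL; }
    if (V[n - 1] > vmax_last) vmax_last = V[n - 1];
  }
  return vmax_last - v_rest_eff;
}

bool recruited_at(const std::vector<double> &ve_unit, double amp,
                  double pulse_ms, double dt_pulse, double dt_post,
                  double horizon_ms, const AxonParams &P) {
  bool div = false;
  double dep = run_once(ve_unit, amp, pulse_ms, dt_pulse, dt_post,
                        horizon_ms, P, &div);
  if (div) stop("axon model diverged at amplitude %f uA", amp);
  // action potential at the last node: overshoot past 0 mV (i.e. > 80 mV
  // depolarisation from rest)
  return dep > 80.0;
}

} // namespace

// [[Rcpp::export]]
bool axon_recruited_cpp(NumericVector ve_unit, double amp_uA,
                        double fiber_d_um, double pulse_us,
                        double dt_pulse_us = 1.0, double dt_post_us = 5.0,
                        double horizon_ms = 3.0) {
  AxonParams P = default_params(fiber_d_um, ve_unit.size());
  std::vector<double> ve(ve_unit.begin(), ve_unit.end());
  return recruited_at(ve, amp_uA, pulse_us / 1000.0, dt_pulse_us / 1000.0,
                      dt_post_us / 1000.0, horizon_ms, P);
}

// Threshold current amplitude (uA) by doubling bracket + bisection to a
// relative tolerance; returns NA if not recruitable below amp_cap.
// [[Rcpp::export]]
double axon_threshold_cpp(NumericVector ve_unit, double fiber_d_um,
                          double pulse_us, double amp_cap = 1e4,
                          double rel_tol = 0.01,
                          double dt_pulse_us = 1.0, double dt_post_us = 5.0,
                          double horizon_ms = 3.0) {
  AxonParams P = default_params(fiber_d_um, ve_unit.size());
  std::vector<double> ve(ve_unit.begin(), ve_unit.end());
  double pulse_ms = pulse_us / 1000.0;
  double dtp = dt_pulse_us / 1000.0, dta = dt_post_us / 1000.0;

  double hi = 1.0, lo = 0.0;
  while (!recruited_at(ve, hi, pulse_ms, dtp, dta, horizon_ms, P)) {
    lo = hi;
    hi *= 2.0;
    if (hi > amp_cap) return NA_REAL;
  }
  while ((hi - lo) / hi > rel_tol) {
    double mid = 0.5 * (hi + lo);
    if (recruited_at(ve, mid, pulse_ms, dtp, dta, horizon_ms, P)) hi = mid;
    else lo = mid;
  }
  return hi;
}
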