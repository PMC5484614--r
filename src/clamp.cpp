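#include <Rcpp.h>
using namespace Rcpp;

// Single-compartment voltage clamp with access resistance in series.
// Units: mV, ms, pA, nS, pF, GOhm.  Recorded current I = (Vcmd - Vm) / Rs.
//
// Membrane ODE (exponential Euler, unconditionally stable):
//   Cm dVm/dt = (Vcmd - Vm)/Rs - Ileak - INa - Idrug - Isyn
// Na+ channel: Hodgkin-Huxley style m^3 h with voltage-dependent steady
// states and fixed time constants. AMPAR limb optionally carries a
// polyamine-block open fraction f(V) = 1/(1 + exp((V - Vh)/k)).
//
// wash_ampa / wash_kar: per-sample bath agonist occupancy (0..1) driving the
// AMPAR / kainate-receptor conductances; gsyn: per-sample synaptic (AMPAR)
// conductance in nS; any of them may be length 0 (treated as absent).

// [[Rcpp::export]]
NumericVector clamp_integrate_cpp(NumericVector vcmd, double dt_ms, int n_sub,
                                  double cm_pf, double rs_gohm, double rm_gohm,
                                  double e_leak,
                                  double gna_ns, double e_na,
                                  double vhalf_m, double k_m, double tau_m,
                                  double vhalf_h, double k_h, double tau_h,
                                  double ga_ns, double gk_ns, double e_glu,
                                  NumericVector wash_ampa,
                                  NumericVector wash_kar,
                                  NumericVector gsyn_ns,
                                  bool rectify, double vh_rect, double k_rect) {
  const int n = vcmd.size();
  if (n < 1) stop("empty command waveform");
  if (n_sub < 1) stop("n_sub must be >= 1");
  if (cm_pf <= 0 || rs_gohm <= 0 || rm_gohm <= 0)
    stop("Cm, Rs and Rm must be positive");
  const bool has_wa = wash_ampa.size() == n;
  const bool has_wk = wash_kar.size() == n;
  const bool has_syn = gsyn_ns.size() == n;
  if (wash_ampa.size() != 0 && !has_wa) stop("wash_ampa length mismatch");
  if (wash_kar.size() != 0 && !has_wk) stop("wash_kar length mismatch");
  if (gsyn_ns.size() != 0 && !has_syn) stop("gsyn length mismatch");

  const double g_acc = 1.0 / rs_gohm;   // nS
  const double g_leak = 1.0 / rm_gohm;  // nS
  const double dt_sub = dt_ms / n_sub;
  const double rel_m = 1.0 - std::exp(-dt_sub / tau_m);
  const double rel_h = 1.0 - std::exp(-dt_sub / tau_h);

  // start at the passive steady state of the first command level
  double v = (vcmd[0] * g_acc + g_leak * e_leak) / (g_acc + g_leak);
  double m = 1.0 / (1.0 + std::exp(-(v - vhalf_m) / k_m));
  double h = 1.0 / (1.0 + std::exp((v - vhalf_h) / k_h));

  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    out[i] = (vcmd[i] - v) * g_acc;
    const double wa = has_wa ? wash_ampa[i] : 0.0;
    const double wk = has_wk ? wash_kar[i] : 0.0;
    const double gs = has_syn ? gsyn_ns[i] : 0.0;
    for (int s = 0; s < n_sub; ++s) {
      double f = 1.0;
      if (rectify) f = 1.0 / (1.0 + std::exp((v - vh_rect) / k_rect));
      const double g_ampa = (ga_ns * wa + gs) * f;
      const double g_kar = gk_ns * wk;
      double gna = 0.0;
      if (gna_ns > 0.0) {
        const double minf = 1.0 / (1.0 + std::exp(-(v - vhalf_m) / k_m));
        const double hinf = 1.0 / (1.0 + std::exp((v - vhalf_h) / k_h));
        m += (minf - m) * rel_m;
        h += (hinf - h) * rel_h;
        gna = gna_ns * m * m * m * h;
      }
      const double g_tot = g_acc + g_leak + gna + g_ampa + g_kar;
      const double i_src = vcmd[i] * g_acc + g_leak * e_leak + gna * e_na +
                           (g_ampa + g_kar) * e_glu;
      const double vinf = i_src / g_tot;
      v = vinf + (v - vinf) * std::exp(-dt_sub * g_tot / cm_pf);
      if (!std::isfinite(v) || std::fabs(v) > 500.0)
        stop("unstable integration: membrane potential diverged (reduce the step size)");
    }
  }
  return out;
}
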