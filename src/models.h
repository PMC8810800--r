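#ifndef BACNAVSIM_MODELS_H
#define BACNAVSIM_MODELS_H

#include <cmath>
#include <cstddef>

namespace bacnavsim {

// overflow-guarded exponential: clamps the argument to +-700 so that
// steep Boltzmann slope factors (0.2351, 0.1281 mV) never overflow a double
inline double gexp(double x) {
  if (x > 700.0) x = 700.0;
  else if (x < -700.0) x = -700.0;
  return std::exp(x);
}

// ---- BacNav (NavSheP D60A / h2SheP) gating -------------------------------
inline double bacnav_tau_m(double v) {
  return 34.65 / (gexp((v + 43.47) / 14.36) + gexp(-(v + 15.75) / 0.2351)) + 1.66;
}
inline double bacnav_tau_h(double v) {
  return 107.8 / (gexp((v + 27.15) / 0.1281) + gexp(-(v + 25.63) / 25.19)) + 9.593;
}
inline double bacnav_m_inf(double v) {
  return 1.0 / (1.0 + gexp((-22.5 - v) / 2.704));
}
inline double bacnav_h_inf(double v) {
  return 1.0 / (1.0 + gexp((v + 77.05) / 10.64));
}

// Rush-Larsen exact relaxation of a Hodgkin-Huxley gate
inline double rl(double g, double ginf, double tau, double dt) {
  return ginf + (g - ginf) * std::exp(-dt / tau);
}

struct Model {
  int ns;  // number of state variables (Vm is state 0, mV)
  int np;  // number of parameters
  int nc;  // number of reported currents (last entry is the total ionic current)
  const char* const* state_names;
  const char* const* param_names;
  const char* const* current_names;
  void (*init)(double* y);
  void (*default_params)(double* p);
  // Computes membrane currents (uA/uF) at the current state, fills cur[0..nc-1]
  // (cur[nc-1] = total), then advances all internal states (gates,
  // concentrations) by dt at fixed Vm. Returns the total ionic current.
  double (*step)(double* y, const double* p, double dt, double* cur);
};

const Model* get_model(const char* name);

}  // namespace bacnavsim

#endif
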