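// Two-variable excitable toy cell (Aliev-Panfilov form) used as a fast
// verification fixture for the solvers: known threshold behavior, APD from a
// fine-step oracle, and classic sqrt(D) scaling of cable conduction velocity.
// The dimensionless excitation variable u is mapped to a voltage-like scale
// Vm = v_rest + v_amp * u so the toy plugs into the same monodomain drivers.

#include "models.h"

namespace bacnavsim {

static const char* toy_states[] = { "vm", "w" };

static const char* toy_params[] = {
  "k", "a", "eps0", "mu1", "mu2", "t_scale", "v_rest", "v_amp"
};

static const char* toy_currents[] = { "I_total" };

static void toy_init(double* y) {
  y[0] = -80.0;  // u = 0 at v_rest
  y[1] = 0.0;
}

static void toy_defaults(double* p) {
  p[0] = 8.0;    // k
  p[1] = 0.15;   // a, excitation threshold
  p[2] = 0.002;  // eps0
  p[3] = 0.2;    // mu1
  p[4] = 0.3;    // mu2
  p[5] = 12.9;   // ms per dimensionless time unit
  p[6] = -80.0;  // v_rest (mV)
  p[7] = 100.0;  // v_amp (mV)
}

static double toy_step(double* y, const double* p, double dt, double* cur) {
  const double k = p[0], a = p[1], eps0 = p[2], mu1 = p[3], mu2 = p[4];
  const double ts = p[5], vrest = p[6], vamp = p[7];
  double u = (y[0] - vrest) / vamp;
  double w = y[1];
  double du = (-k * u * (u - a) * (u - 1.0) - u * w) / ts;
  double eps = (eps0 + mu1 * w / (u + mu2)) / ts;
  double dw = eps * (-w - k * u * (u - a - 1.0));
  double Itot = -vamp * du;  // uA/uF convention: dVm/dt = -I_total
  if (cur) cur[0] = Itot;
  y[1] = w + dt * dw;
  return Itot;
}

extern const Model toy_model;
const Model toy_model = {
  2, 8, 1, toy_states, toy_params, toy_currents,
  toy_init, toy_defaults, toy_step
};

}  // namespace bacnavsim
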