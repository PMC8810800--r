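// Guinea-pig adult ventricular myocyte model of the Luo-Rudy lineage:
// Luo-Rudy (1991) fast sodium, slow inward (Ca), time-independent potassium,
// plateau and background currents, with the delayed rectifier split into
// rapid (IKr) and slow (IKs) components (Zeng-Rudy forms) and a two-gate
// transient outward current (Ito) so that transmural layers can be built by
// setting per-cell max Ito and the IKs:IKr conductance ratio. Includes the
// added BacNav current and a divisor on the tau of the fast inactivation
// gate h of INa for Brugada-type accelerated inactivation.
// Units: mV, ms, uA/uF, mS/uF, mM.

#include "models.h"

namespace bacnavsim {

static const char* gpv_states[] = {
  "vm", "m", "h", "j", "d", "f", "cai", "xr", "xs", "r_to", "s_to",
  "m_bac", "h_bac"
};

static const char* gpv_params[] = {
  "gNa_scale", "gto_max", "gKs", "gKr", "gK1_scale", "gsi_scale",
  "tauh_factor", "g_bacnav", "e_bacnav"
};

static const char* gpv_currents[] = {
  "I_Na", "I_si", "I_Kr", "I_Ks", "I_K1", "I_Kp", "I_to", "I_b",
  "I_BacNav", "I_total"
};

static void gpv_init(double* y) {
  y[0] = -84.5; y[1] = 0.0017; y[2] = 0.983; y[3] = 0.995;
  y[4] = 0.003; y[5] = 0.994; y[6] = 1.0e-4;
  y[7] = 0.0; y[8] = 0.0; y[9] = 0.0; y[10] = 1.0;
  y[11] = bacnav_m_inf(y[0]);
  y[12] = bacnav_h_inf(y[0]);
}

static void gpv_defaults(double* p) {
  const double gKr0 = 0.02614;  // sqrt(ko/5.4) = 1 at ko = 5.4
  p[0] = 1.0;
  p[1] = 0.0;          // no Ito in the generic (non-transmural) cell
  p[2] = 11.0 * gKr0;  // endocardial-like IKs:IKr ratio by default
  p[3] = gKr0;
  p[4] = 1.0; p[5] = 1.0; p[6] = 1.0; p[7] = 0.0;
  p[8] = NAN;  // NaN -> fixed-concentration sodium Nernst potential
}

static double gpv_step(double* y, const double* p, double dt, double* cur) {
  const double ko = 5.4, ki = 145.0, nao = 140.0, nai = 18.0;
  const double RTF = 8314.0 * 310.0 / 96485.0;
  const double ENa = RTF * std::log(nao / nai);          // ~ +54.4 mV
  const double EK = RTF * std::log(ko / ki);
  const double PKNa = 0.01833;
  const double EKs = RTF * std::log((ko + PKNa * nao) / (ki + PKNa * nai));

  double v = y[0];
  double m = y[1], h = y[2], j = y[3], d = y[4], f = y[5], cai = y[6];
  double xr = y[7], xs = y[8], r_to = y[9], s_to = y[10];
  double mb = y[11], hb = y[12];

  // INa (Luo-Rudy 1991)
  double am = (std::fabs(v + 47.13) < 1e-6)
                  ? 3.2
                  : 0.32 * (v + 47.13) / (1.0 - gexp(-0.1 * (v + 47.13)));
  double bm = 0.08 * gexp(-v / 11.0);
  double ah, bh, aj, bj;
  if (v < -40.0) {
    ah = 0.135 * gexp(-(80.0 + v) / 6.8);
    bh = 3.56 * gexp(0.079 * v) + 3.1e5 * gexp(0.35 * v);
    aj = (-1.2714e5 * gexp(0.2444 * v) - 3.474e-5 * gexp(-0.04391 * v)) *
         (v + 37.78) / (1.0 + gexp(0.311 * (v + 79.23)));
    bj = 0.1212 * gexp(-0.01052 * v) / (1.0 + gexp(-0.1378 * (v + 40.14)));
  } else {
    ah = 0.0;
    bh = 1.0 / (0.13 * (1.0 + gexp(-(v + 10.66) / 11.1)));
    aj = 0.0;
    bj = 0.3 * gexp(-2.535e-7 * v) / (1.0 + gexp(-0.1 * (v + 32.0)));
  }
  double GNa = 23.0 * p[0];
  double INa = GNa * m * m * m * h * j * (v - ENa);

  // Isi (slow inward Ca current, LR91) with dynamic cai
  double ad = 0.095 * gexp(-0.01 * (v - 5.0)) / (1.0 + gexp(-0.072 * (v - 5.0)));
  double bd = 0.07 * gexp(-0.017 * (v + 44.0)) / (1.0 + gexp(0.05 * (v + 44.0)));
  double af = 0.012 * gexp(-0.008 * (v + 28.0)) / (1.0 + gexp(0.15 * (v + 28.0)));
  double bf = 0.0065 * gexp(-0.02 * (v + 30.0)) / (1.0 + gexp(-0.2 * (v + 30.0)));
  double Esi = 7.7 - 13.0287 * std::log(cai);
  double Isi = 0.09 * p[5] * d * f * (v - Esi);

  // IKr (Zeng-Rudy): activation gate xr, instantaneous rectification r
  double xrss = 1.0 / (1.0 + gexp(-(v + 21.5) / 7.5));
  double axr = (std::fabs(v + 14.2) < 1e-6)
                   ? 0.00138 / 0.123
                   : 0.00138 * (v + 14.2) / (1.0 - gexp(-0.123 * (v + 14.2)));
  double bxr = (std::fabs(v + 38.9) < 1e-6)
                   ? 0.00061 / 0.145
                   : 0.00061 * (v + 38.9) / (gexp(0.145 * (v + 38.9)) - 1.0);
  double txr = 1.0 / (axr + bxr);
  double rgate = 1.0 / (1.0 + gexp((v + 9.0) / 22.4));
  double IKr = p[3] * std::sqrt(ko / 5.4) * xr * rgate * (v - EK);

  // IKs (Zeng-Rudy): activation gate squared
  double xsss = 1.0 / (1.0 + gexp(-(v - 1.5) / 16.7));
  double axs = (std::fabs(v + 30.0) < 1e-6)
                   ? 7.19e-5 / 0.148
                   : 7.19e-5 * (v + 30.0) / (1.0 - gexp(-0.148 * (v + 30.0)));
  double bxs = (std::fabs(v + 30.0) < 1e-6)
                   ? 1.31e-4 / 0.0687
                   : 1.31e-4 * (v + 30.0) / (gexp(0.0687 * (v + 30.0)) - 1.0);
  double txs = 1.0 / (axs + bxs);
  double IKs = p[2] * xs * xs * (v - EKs);

  // IK1 (LR91)
  double ak1 = 1.02 / (1.0 + gexp(0.2385 * (v - EK - 59.215)));
  double bk1 = (0.49124 * gexp(0.08032 * (v - EK + 5.476)) +
                gexp(0.06175 * (v - EK - 594.31))) /
               (1.0 + gexp(-0.5143 * (v - EK + 4.753)));
  double gK1 = 0.6047 * std::sqrt(ko / 5.4) * p[4];
  double IK1 = gK1 * (ak1 / (ak1 + bk1)) * (v - EK);

  // IKp and background (LR91)
  double Kp = 1.0 / (1.0 + gexp((7.488 - v) / 5.98));
  double IKp = 0.0183 * Kp * (v - EK);
  double Ib = 0.03921 * (v + 59.87);

  // Ito: fast-activating, fast-inactivating two-gate current; activation
  // midpoint near 0 mV so the current is engaged at this host's plateau
  double rss = 1.0 / (1.0 + gexp((10.0 - v) / 9.0));
  double tr = 9.5 * gexp(-(v + 40.0) * (v + 40.0) / 1800.0) + 0.8;
  double sss = 1.0 / (1.0 + gexp((v + 20.0) / 5.0));
  double ts = 85.0 * gexp(-(v + 45.0) * (v + 45.0) / 320.0) +
              5.0 / (1.0 + gexp((v - 20.0) / 5.0)) + 3.0;
  double Ito = p[1] * r_to * s_to * (v - EK);

  // BacNav
  double e_bac = std::isnan(p[8]) ? ENa : p[8];
  double IBacNav = p[7] * mb * hb * (v - e_bac);

  double Itot = INa + Isi + IKr + IKs + IK1 + IKp + Ito + Ib + IBacNav;

  if (cur) {
    cur[0] = INa; cur[1] = Isi; cur[2] = IKr; cur[3] = IKs; cur[4] = IK1;
    cur[5] = IKp; cur[6] = Ito; cur[7] = Ib; cur[8] = IBacNav; cur[9] = Itot;
  }

  // gate updates (Rush-Larsen); tauh_factor accelerates fast inactivation
  double th = (1.0 / (ah + bh)) / p[6];
  y[1] = rl(m, am / (am + bm), 1.0 / (am + bm), dt);
  y[2] = rl(h, ah / (ah + bh), th, dt);
  y[3] = rl(j, aj / (aj + bj), 1.0 / (aj + bj), dt);
  y[4] = rl(d, ad / (ad + bd), 1.0 / (ad + bd), dt);
  y[5] = rl(f, af / (af + bf), 1.0 / (af + bf), dt);
  y[7] = rl(xr, xrss, txr, dt);
  y[8] = rl(xs, xsss, txs, dt);
  y[9] = rl(r_to, rss, tr, dt);
  y[10] = rl(s_to, sss, ts, dt);
  y[11] = rl(mb, bacnav_m_inf(v), bacnav_tau_m(v), dt);
  y[12] = rl(hb, bacnav_h_inf(v), bacnav_tau_h(v), dt);
  double dcai = -1.0e-4 * Isi + 0.07 * (1.0e-4 - cai);
  y[6] = cai + dt * dcai;
  if (y[6] < 1e-9) y[6] = 1e-9;

  return Itot;
}

extern const Model gpv_model;
const Model gpv_model = {
  13, 9, 10, gpv_states, gpv_params, gpv_currents,
  gpv_init, gpv_defaults, gpv_step
};

}  // namespace bacnavsim
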