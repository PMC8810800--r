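// O'Hara-Rudy (2011) human adult ventricular myocyte model, endocardial
// parameterization, transcribed from the published equations, with an added
// BacNav (h2SheP) current carried by one activation and one inactivation gate.
// Units: mV, ms, uA/uF, mS/uF, mM.
//
// All purely voltage-dependent quantities (gate targets, Rush-Larsen
// relaxation factors for the integrator's fixed dt, GHK and exchanger shape
// factors) are tabulated on a 0.05 mV grid and linearly interpolated, the
// standard acceleration for monodomain tissue runs; concentration-dependent
// algebra is evaluated directly.

#include <vector>
#include "models.h"

namespace bacnavsim {

static const char* ord_states[] = {
  "vm", "nai", "nass", "ki", "kss", "cai", "cass", "cansr", "cajsr",
  "m", "hf", "hs", "j", "hsp", "jp", "mL", "hL", "hLp",
  "a", "iF", "iS", "ap", "iFp", "iSp",
  "d", "ff", "fs", "fcaf", "fcas", "jca", "nca", "ffp", "fcafp",
  "xrf", "xrs", "xs1", "xs2", "xk1", "Jrelnp", "Jrelp", "CaMKt",
  "m_bac", "h_bac"
};

static const char* ord_params[] = {
  "gNa_scale", "gNaL_scale", "gto_scale", "gKs_scale", "gKr_scale",
  "gK1_scale", "gCaL_scale", "g_bacnav", "e_bacnav"
};

static const char* ord_currents[] = {
  "I_Na", "I_NaL", "I_to", "I_CaL", "I_Kr", "I_Ks", "I_K1",
  "I_NaCa", "I_NaK", "I_other", "I_BacNav", "I_total"
};

// published steady-state initial conditions (1 Hz, endo); runs re-equilibrate
static void ord_init(double* y) {
  const double y0[43] = {
    -87.84, 7.23, 7.23, 143.79, 143.79, 8.54e-5, 8.43e-5, 1.61, 1.56,
    0.0074621, 0.692591, 0.692574, 0.692477, 0.448501, 0.692413,
    0.000194015, 0.496116, 0.265885,
    0.00101185, 0.999542, 0.589579, 0.000515567, 0.999542, 0.641861,
    2.43015e-9, 1.0, 0.910671, 1.0, 0.99982, 0.999977, 0.00267171, 1.0, 1.0,
    8.26608e-6, 0.453268, 0.270492, 0.0001963, 0.996801,
    2.53943e-5, 3.17262e-7, 0.0124065,
    0.0, 0.0
  };
  for (int i = 0; i < 43; ++i) y[i] = y0[i];
  // BacNav gates start at their steady state for the resting potential
  y[41] = bacnav_m_inf(y[0]);
  y[42] = bacnav_h_inf(y[0]);
}

static void ord_defaults(double* p) {
  p[0] = 1.0; p[1] = 1.0; p[2] = 1.0; p[3] = 1.0; p[4] = 1.0;
  p[5] = 1.0; p[6] = 1.0; p[7] = 0.0;
  p[8] = NAN;  // NaN -> sodium Nernst potential from nai/nao
}

namespace {

const double R = 8314.0, T = 310.0, F = 96485.0;

// tabulated voltage-dependent quantities
enum Q {
  Q_mss, Q_rl_m, Q_hss, Q_rl_hf, Q_rl_hs, Q_rl_j, Q_hssp, Q_rl_hsp, Q_rl_jp,
  Q_mLss, Q_rl_mL, Q_hLss, Q_hLssp,
  Q_ass, Q_rl_a, Q_iss, Q_rl_iF, Q_rl_iS, Q_assp, Q_rl_iFp, Q_rl_iSp,
  Q_dss, Q_rl_d, Q_fss, Q_rl_ff, Q_rl_fs, Q_rl_fcaf, Q_rl_fcas, Q_rl_ffp,
  Q_rl_fcafp, Q_AiF, Q_Afcaf,
  Q_xrss, Q_rl_xrf, Q_rl_xrs, Q_Axrf, Q_rkr,
  Q_xs1ss, Q_rl_xs1, Q_rl_xs2,
  Q_xk1ss, Q_rl_xk1, Q_rk1, Q_xkb,
  Q_hca, Q_hna, Q_Knai, Q_Knao,
  Q_e1v, Q_e2v, Q_A1, Q_A2,
  Q_mbss, Q_rl_mb, Q_hbss, Q_rl_hb,
  NQ
};

struct OrdLut {
  static constexpr double VMIN = -150.0, VMAX = 100.0, DV = 0.05;
  static constexpr int N = (int)((VMAX - VMIN) / DV) + 1;
  double dt = -1.0;
  double rl_hL = 0, rl_hLp = 0, rl_jca = 0;  // constant time constants
  std::vector<double> tab;

  // all voltage-only quantities of the model at one potential
  static void rates(double v, double dt, double* q) {
    const double ko = 5.4;
    double mss = 1.0 / (1.0 + gexp(-(v + 39.57) / 9.871));
    double tm = 1.0 / (6.765 * gexp((v + 11.64) / 34.77) +
                       8.552 * gexp(-(v + 77.42) / 5.955));
    double hss = 1.0 / (1.0 + gexp((v + 82.90) / 6.086));
    double thf = 1.0 / (1.432e-5 * gexp(-(v + 1.196) / 6.285) +
                        6.149 * gexp((v + 0.5096) / 20.27));
    double ths = 1.0 / (0.009794 * gexp(-(v + 17.95) / 28.05) +
                        0.3343 * gexp((v + 5.730) / 56.66));
    double tj = 2.038 + 1.0 / (0.02136 * gexp(-(v + 100.6) / 8.281) +
                               0.3052 * gexp((v + 0.9941) / 38.45));
    double hssp = 1.0 / (1.0 + gexp((v + 89.1) / 6.086));
    double mLss = 1.0 / (1.0 + gexp(-(v + 42.85) / 5.264));
    double hLss = 1.0 / (1.0 + gexp((v + 87.61) / 7.488));
    double hLssp = 1.0 / (1.0 + gexp((v + 93.81) / 7.488));
    double ass = 1.0 / (1.0 + gexp(-(v - 14.34) / 14.82));
    double ta = 1.0515 /
                (1.0 / (1.2089 * (1.0 + gexp(-(v - 18.4099) / 29.3814))) +
                 3.5 / (1.0 + gexp((v + 100.0) / 29.3814)));
    double iss = 1.0 / (1.0 + gexp((v + 43.94) / 5.711));
    double tiF = 4.562 + 1.0 / (0.3933 * gexp(-(v + 100.0) / 100.0) +
                                0.08004 * gexp((v + 50.0) / 16.59));
    double tiS = 23.62 + 1.0 / (0.001416 * gexp(-(v + 96.52) / 59.05) +
                                1.780e-8 * gexp((v + 114.1) / 8.079));
    double AiF = 1.0 / (1.0 + gexp((v - 213.6) / 151.2));
    double assp = 1.0 / (1.0 + gexp(-(v - 24.34) / 14.82));
    double dti_develop = 1.354 + 1.0e-4 / (gexp((v - 167.4) / 15.89) +
                                           gexp(-(v - 12.23) / 0.2154));
    double dti_recover = 1.0 - 0.5 / (1.0 + gexp((v + 70.0) / 20.0));
    double tiFp = dti_develop * dti_recover * tiF;
    double tiSp = dti_develop * dti_recover * tiS;
    double dss = 1.0 / (1.0 + gexp(-(v + 3.940) / 4.230));
    double td = 0.6 + 1.0 / (gexp(-0.05 * (v + 6.0)) + gexp(0.09 * (v + 14.0)));
    double fss = 1.0 / (1.0 + gexp((v + 19.58) / 3.696));
    double tff = 7.0 + 1.0 / (0.0045 * gexp(-(v + 20.0) / 10.0) +
                              0.0045 * gexp((v + 20.0) / 10.0));
    double tfs = 1000.0 + 1.0 / (0.000035 * gexp(-(v + 5.0) / 4.0) +
                                 0.000035 * gexp((v + 5.0) / 6.0));
    double tfcaf = 7.0 + 1.0 / (0.04 * gexp(-(v - 4.0) / 7.0) +
                                0.04 * gexp((v - 4.0) / 7.0));
    double tfcas = 100.0 + 1.0 / (0.00012 * gexp(-v / 3.0) +
                                  0.00012 * gexp(v / 7.0));
    double Afcaf = 0.3 + 0.6 / (1.0 + gexp((v - 10.0) / 10.0));
    double xrss = 1.0 / (1.0 + gexp(-(v + 8.337) / 6.789));
    double txrf = 12.98 + 1.0 / (0.3652 * gexp((v - 31.66) / 3.869) +
                                 4.123e-5 * gexp(-(v - 47.78) / 20.38));
    double txrs = 1.865 + 1.0 / (0.06629 * gexp((v - 34.70) / 7.355) +
                                 1.128e-5 * gexp(-(v - 29.74) / 25.94));
    double Axrf = 1.0 / (1.0 + gexp((v + 54.81) / 38.21));
    double rkr = 1.0 / (1.0 + gexp((v + 55.0) / 75.0)) /
                 (1.0 + gexp((v - 10.0) / 30.0));
    double xs1ss = 1.0 / (1.0 + gexp(-(v + 11.60) / 8.932));
    double txs1 = 817.3 + 1.0 / (2.326e-4 * gexp((v + 48.28) / 17.80) +
                                 0.001292 * gexp(-(v + 210.0) / 230.0));
    double txs2 = 1.0 / (0.01 * gexp((v - 50.0) / 20.0) +
                         0.0193 * gexp(-(v + 66.54) / 31.0));
    double xk1ss = 1.0 / (1.0 + gexp(-(v + 2.5538 * ko + 144.59) /
                                     (1.5692 * ko + 3.8115)));
    double txk1 = 122.2 / (gexp(-(v + 127.2) / 20.36) +
                           gexp((v + 236.8) / 69.33));
    double rk1 = 1.0 / (1.0 + gexp((v + 105.8 - 2.6 * ko) / 9.493));
    double xkb = 1.0 / (1.0 + gexp(-(v - 14.48) / 18.34));
    const double qna = 0.5224, qca = 0.1670;
    double hca = gexp(qca * v * F / (R * T));
    double hna = gexp(qna * v * F / (R * T));
    const double Knai0 = 9.073, Knao0 = 27.78, delta = -0.1550;
    double Knai = Knai0 * gexp(delta * v * F / (3.0 * R * T));
    double Knao = Knao0 * gexp((1.0 - delta) * v * F / (3.0 * R * T));
    double vsafe = (std::fabs(v) < 1e-6) ? 1e-6 : v;
    double vfrt = vsafe * F / (R * T);
    double vffrt = vsafe * F * F / (R * T);
    double e1v = gexp(vfrt), e2v = gexp(2.0 * vfrt);
    double A1 = vffrt / (e1v - 1.0);
    double A2 = 4.0 * vffrt / (e2v - 1.0);
    double rl = 0.0;  // helper lambda-free: computed inline below

    q[Q_mss] = mss;      q[Q_rl_m] = std::exp(-dt / tm);
    q[Q_hss] = hss;      q[Q_rl_hf] = std::exp(-dt / thf);
    q[Q_rl_hs] = std::exp(-dt / ths);
    q[Q_rl_j] = std::exp(-dt / tj);
    q[Q_hssp] = hssp;    q[Q_rl_hsp] = std::exp(-dt / (3.0 * ths));
    q[Q_rl_jp] = std::exp(-dt / (1.46 * tj));
    q[Q_mLss] = mLss;    q[Q_rl_mL] = std::exp(-dt / tm);
    q[Q_hLss] = hLss;    q[Q_hLssp] = hLssp;
    q[Q_ass] = ass;      q[Q_rl_a] = std::exp(-dt / ta);
    q[Q_iss] = iss;      q[Q_rl_iF] = std::exp(-dt / tiF);
    q[Q_rl_iS] = std::exp(-dt / tiS);
    q[Q_assp] = assp;    q[Q_rl_iFp] = std::exp(-dt / tiFp);
    q[Q_rl_iSp] = std::exp(-dt / tiSp);
    q[Q_dss] = dss;      q[Q_rl_d] = std::exp(-dt / td);
    q[Q_fss] = fss;      q[Q_rl_ff] = std::exp(-dt / tff);
    q[Q_rl_fs] = std::exp(-dt / tfs);
    q[Q_rl_fcaf] = std::exp(-dt / tfcaf);
    q[Q_rl_fcas] = std::exp(-dt / tfcas);
    q[Q_rl_ffp] = std::exp(-dt / (2.5 * tff));
    q[Q_rl_fcafp] = std::exp(-dt / (2.5 * tfcaf));
    q[Q_AiF] = AiF;      q[Q_Afcaf] = Afcaf;
    q[Q_xrss] = xrss;    q[Q_rl_xrf] = std::exp(-dt / txrf);
    q[Q_rl_xrs] = std::exp(-dt / txrs);
    q[Q_Axrf] = Axrf;    q[Q_rkr] = rkr;
    q[Q_xs1ss] = xs1ss;  q[Q_rl_xs1] = std::exp(-dt / txs1);
    q[Q_rl_xs2] = std::exp(-dt / txs2);
    q[Q_xk1ss] = xk1ss;  q[Q_rl_xk1] = std::exp(-dt / txk1);
    q[Q_rk1] = rk1;      q[Q_xkb] = xkb;
    q[Q_hca] = hca;      q[Q_hna] = hna;
    q[Q_Knai] = Knai;    q[Q_Knao] = Knao;
    q[Q_e1v] = e1v;      q[Q_e2v] = e2v;
    q[Q_A1] = A1;        q[Q_A2] = A2;
    q[Q_mbss] = bacnav_m_inf(v);
    q[Q_rl_mb] = std::exp(-dt / bacnav_tau_m(v));
    q[Q_hbss] = bacnav_h_inf(v);
    q[Q_rl_hb] = std::exp(-dt / bacnav_tau_h(v));
    (void)rl;
  }

  void build(double dt_new) {
    dt = dt_new;
    tab.resize((size_t)N * NQ);
    for (int i = 0; i < N; ++i) {
      rates(VMIN + i * DV, dt, &tab[(size_t)i * NQ]);
    }
    rl_hL = std::exp(-dt / 200.0);
    rl_hLp = std::exp(-dt / 600.0);
    rl_jca = std::exp(-dt / 75.0);
  }
};

OrdLut lut;

}  // namespace

static double ord_step(double* y, const double* p, double dt, double* cur) {
  const double nao = 140.0, cao = 1.8, ko = 5.4;
  const double L = 0.01, rad = 0.0011;
  const double vcell = 1000.0 * 3.14 * rad * rad * L;
  const double Ageo = 2.0 * 3.14 * rad * rad + 2.0 * 3.14 * rad * L;
  const double Acap = 2.0 * Ageo;
  const double vmyo = 0.68 * vcell, vnsr = 0.0552 * vcell,
               vjsr = 0.0048 * vcell, vss = 0.02 * vcell;

  double v = y[0];
  double nai = y[1], nass = y[2], ki = y[3], kss = y[4];
  double cai = y[5], cass = y[6], cansr = y[7], cajsr = y[8];
  double m = y[9], hf = y[10], hs = y[11], j = y[12], hsp = y[13], jp = y[14];
  double mL = y[15], hL = y[16], hLp = y[17];
  double a = y[18], iF = y[19], iS = y[20], ap = y[21], iFp = y[22],
         iSp = y[23];
  double d = y[24], ff = y[25], fs = y[26], fcaf = y[27], fcas = y[28],
         jca = y[29], nca = y[30], ffp = y[31], fcafp = y[32];
  double xrf = y[33], xrs = y[34], xs1 = y[35], xs2 = y[36], xk1 = y[37];
  double Jrelnp = y[38], Jrelp = y[39], CaMKt = y[40];
  double mb = y[41], hb = y[42];

  // interpolated voltage-dependent quantities (RL factors valid for the
  // table's dt; dt == 0 calls only read current shapes)
  if (lut.dt != dt && dt > 0.0) lut.build(dt);
  if (lut.dt < 0.0) lut.build(1.0);
  double vc = v;
  if (vc < OrdLut::VMIN) vc = OrdLut::VMIN;
  if (vc > OrdLut::VMAX) vc = OrdLut::VMAX;
  double pos = (vc - OrdLut::VMIN) / OrdLut::DV;
  int i0 = (int)pos;
  if (i0 >= OrdLut::N - 1) i0 = OrdLut::N - 2;
  double w1 = pos - i0, w0 = 1.0 - w1;
  const double* qa = &lut.tab[(size_t)i0 * NQ];
  const double* qb = qa + NQ;
  double q[NQ];
  for (int k = 0; k < NQ; ++k) q[k] = w0 * qa[k] + w1 * qb[k];

  // CaMK
  const double KmCaMK = 0.15, aCaMK = 0.05, bCaMK = 0.00068,
               CaMKo = 0.05, KmCaM = 0.0015;
  double CaMKb = CaMKo * (1.0 - CaMKt) / (1.0 + KmCaM / cass);
  double CaMKa = CaMKb + CaMKt;
  double fphos = 1.0 / (1.0 + KmCaMK / CaMKa);

  double ENa = (R * T / F) * std::log(nao / nai);
  double EK = (R * T / F) * std::log(ko / ki);
  const double PKNa = 0.01833;
  double EKs = (R * T / F) * std::log((ko + PKNa * nao) / (ki + PKNa * nai));

  // INa (fast) and INaL
  const double Ahf = 0.99, Ahs = 0.01;
  double h = Ahf * hf + Ahs * hs;
  double hp = Ahf * hf + Ahs * hsp;
  double GNa = 75.0 * p[0];
  double INa = GNa * (v - ENa) * m * m * m *
               ((1.0 - fphos) * h * j + fphos * hp * jp);
  double GNaL = 0.0075 * p[1];
  double INaL = GNaL * (v - ENa) * mL * ((1.0 - fphos) * hL + fphos * hLp);

  // Ito
  double i_gate = q[Q_AiF] * iF + (1.0 - q[Q_AiF]) * iS;
  double ip = q[Q_AiF] * iFp + (1.0 - q[Q_AiF]) * iSp;
  double Gto = 0.02 * p[2];
  double Ito = Gto * (v - EK) *
               ((1.0 - fphos) * a * i_gate + fphos * ap * ip);

  // ICaL / ICaNa / ICaK through the L-type channel
  const double Aff = 0.6, Afs = 0.4;
  double f = Aff * ff + Afs * fs;
  double fca = q[Q_Afcaf] * fcaf + (1.0 - q[Q_Afcaf]) * fcas;
  double fp = Aff * ffp + Afs * fs;
  double fcap = q[Q_Afcaf] * fcafp + (1.0 - q[Q_Afcaf]) * fcas;
  const double Kmn = 0.002, k2n = 1000.0;
  double km2n = jca * 1.0;
  double t4 = 1.0 + Kmn / cass;
  double anca = 1.0 / (k2n / km2n + t4 * t4 * t4 * t4);
  double PhiCaL = q[Q_A2] * (cass * q[Q_e2v] - 0.341 * cao);
  double PhiCaNa = q[Q_A1] * 0.75 * (nass * q[Q_e1v] - nao);
  double PhiCaK = q[Q_A1] * 0.75 * (kss * q[Q_e1v] - ko);
  double PCa = 0.0001 * p[6];
  double PCap = 1.1 * PCa;
  double gate_np = d * (f * (1.0 - nca) + jca * fca * nca);
  double gate_p = d * (fp * (1.0 - nca) + jca * fcap * nca);
  double pmix = (1.0 - fphos) * PCa + fphos * PCap;
  double ICaL = PhiCaL * ((1.0 - fphos) * PCa * gate_np +
                          fphos * PCap * gate_p);
  double ICaNa = 0.00125 * PhiCaNa * ((1.0 - fphos) * PCa * gate_np +
                                      fphos * PCap * gate_p);
  double ICaK = 3.574e-4 * PhiCaK * ((1.0 - fphos) * PCa * gate_np +
                                     fphos * PCap * gate_p);
  (void)pmix;

  // IKr, IKs, IK1
  double xr = q[Q_Axrf] * xrf + (1.0 - q[Q_Axrf]) * xrs;
  double GKr = 0.046 * p[4];
  double IKr = GKr * std::sqrt(ko / 5.4) * xr * q[Q_rkr] * (v - EK);
  double KsCa = 1.0 + 0.6 / (1.0 + std::pow(3.8e-5 / cai, 1.4));
  double GKs = 0.0034 * p[3];
  double IKs = GKs * KsCa * xs1 * xs2 * (v - EKs);
  double GK1 = 0.1908 * p[5];
  double IK1 = GK1 * std::sqrt(ko) * q[Q_rk1] * xk1 * (v - EK);

  // INaCa (Na/Ca exchanger), myoplasmic and subspace components
  const double kna1 = 15.0, kna2 = 5.0, kna3 = 88.12, kasymm = 12.5;
  const double wna = 6.0e4, wca = 6.0e4, wnaca = 5.0e3;
  const double kcaon = 1.5e6, kcaoff = 5.0e3;
  double hca = q[Q_hca], hna = q[Q_hna];
  const double KmCaAct = 150.0e-6;
  const double Gncx = 0.0008;
  const double zca = 2.0, zna = 1.0, zk = 1.0;
  double INaCa_i, INaCa_ss;
  {
    double h1 = 1.0 + nai / kna3 * (1.0 + hna);
    double h2 = (nai * hna) / (kna3 * h1);
    double h3 = 1.0 / h1;
    double h4 = 1.0 + nai / kna1 * (1.0 + nai / kna2);
    double h5 = nai * nai / (h4 * kna1 * kna2);
    double h6 = 1.0 / h4;
    double h7 = 1.0 + nao / kna3 * (1.0 + 1.0 / hna);
    double h8 = nao / (kna3 * hna * h7);
    double h9 = 1.0 / h7;
    double h10 = kasymm + 1.0 + nao / kna1 * (1.0 + nao / kna2);
    double h11 = nao * nao / (h10 * kna1 * kna2);
    double h12 = 1.0 / h10;
    double k1 = h12 * cao * kcaon, k2 = kcaoff;
    double k3p = h9 * wca, k3pp = h8 * wnaca, k3 = k3p + k3pp;
    double k4p = h3 * wca / hca, k4pp = h2 * wnaca, k4 = k4p + k4pp;
    double k5 = kcaoff, k6 = h6 * cai * kcaon;
    double k7 = h5 * h2 * wna, k8 = h8 * h11 * wna;
    double x1 = k2 * k4 * (k7 + k6) + k5 * k7 * (k2 + k3);
    double x2 = k1 * k7 * (k4 + k5) + k4 * k6 * (k1 + k8);
    double x3 = k1 * k3 * (k7 + k6) + k8 * k6 * (k2 + k3);
    double x4 = k2 * k8 * (k4 + k5) + k3 * k5 * (k1 + k8);
    double s = x1 + x2 + x3 + x4;
    double E1 = x1 / s, E2 = x2 / s, E3 = x3 / s, E4 = x4 / s;
    double allo = 1.0 / (1.0 + (KmCaAct / cai) * (KmCaAct / cai));
    double JncxNa = 3.0 * (E4 * k7 - E1 * k8) + E3 * k4pp - E2 * k3pp;
    double JncxCa = E2 * k2 - E1 * k1;
    INaCa_i = 0.8 * Gncx * allo * (zna * JncxNa + zca * JncxCa);
  }
  {
    double h1 = 1.0 + nass / kna3 * (1.0 + hna);
    double h2 = (nass * hna) / (kna3 * h1);
    double h3 = 1.0 / h1;
    double h4 = 1.0 + nass / kna1 * (1.0 + nass / kna2);
    double h5 = nass * nass / (h4 * kna1 * kna2);
    double h6 = 1.0 / h4;
    double h7 = 1.0 + nao / kna3 * (1.0 + 1.0 / hna);
    double h8 = nao / (kna3 * hna * h7);
    double h9 = 1.0 / h7;
    double h10 = kasymm + 1.0 + nao / kna1 * (1.0 + nao / kna2);
    double h11 = nao * nao / (h10 * kna1 * kna2);
    double h12 = 1.0 / h10;
    double k1 = h12 * cao * kcaon, k2 = kcaoff;
    double k3p = h9 * wca, k3pp = h8 * wnaca, k3 = k3p + k3pp;
    double k4p = h3 * wca / hca, k4pp = h2 * wnaca, k4 = k4p + k4pp;
    double k5 = kcaoff, k6 = h6 * cass * kcaon;
    double k7 = h5 * h2 * wna, k8 = h8 * h11 * wna;
    double x1 = k2 * k4 * (k7 + k6) + k5 * k7 * (k2 + k3);
    double x2 = k1 * k7 * (k4 + k5) + k4 * k6 * (k1 + k8);
    double x3 = k1 * k3 * (k7 + k6) + k8 * k6 * (k2 + k3);
    double x4 = k2 * k8 * (k4 + k5) + k3 * k5 * (k1 + k8);
    double s = x1 + x2 + x3 + x4;
    double E1 = x1 / s, E2 = x2 / s, E3 = x3 / s, E4 = x4 / s;
    double allo = 1.0 / (1.0 + (KmCaAct / cass) * (KmCaAct / cass));
    double JncxNa = 3.0 * (E4 * k7 - E1 * k8) + E3 * k4pp - E2 * k3pp;
    double JncxCa = E2 * k2 - E1 * k1;
    INaCa_ss = 0.2 * Gncx * allo * (zna * JncxNa + zca * JncxCa);
  }
  double INaCa = INaCa_i + INaCa_ss;

  // INaK pump
  double INaK;
  {
    const double k1p = 949.5, k1m = 182.4, k2p = 687.2, k2m = 39.4;
    const double k3pc = 1899.0, k3m = 79300.0, k4pc = 639.0, k4m = 40.0;
    double Knai = q[Q_Knai], Knao = q[Q_Knao];
    const double Kki = 0.5, Kko = 0.3582, MgADP = 0.05, MgATP = 9.8;
    const double Kmgatp = 1.698e-7, H = 1.0e-7, eP = 4.2;
    const double Khp = 1.698e-7, Knap = 224.0, Kxkur = 292.0;
    double P = eP / (1.0 + H / Khp + nai / Knap + ki / Kxkur);
    double c3i = 1.0 + nai / Knai, c2i = 1.0 + ki / Kki;
    double c3o = 1.0 + nao / Knao, c2o = 1.0 + ko / Kko;
    double di = c3i * c3i * c3i + c2i * c2i - 1.0;
    double dox = c3o * c3o * c3o + c2o * c2o - 1.0;
    double rni = nai / Knai, rno = nao / Knao;
    double a1 = k1p * rni * rni * rni / di;
    double b1 = k1m * MgADP;
    double a2 = k2p;
    double b2 = k2m * rno * rno * rno / dox;
    double a3 = k3pc * (ko / Kko) * (ko / Kko) / dox;
    double b3 = k3m * P * H / (1.0 + MgATP / Kmgatp);
    double a4 = (k4pc * MgATP / Kmgatp) / (1.0 + MgATP / Kmgatp);
    double b4 = k4m * (ki / Kki) * (ki / Kki) / di;
    double x1 = a4 * a1 * a2 + b2 * b4 * b3 + a2 * b4 * b3 + b3 * a1 * a2;
    double x2 = b2 * b1 * b4 + a1 * a2 * a3 + a3 * b1 * b4 + a2 * a3 * b4;
    double x3 = a2 * a3 * a4 + b3 * b2 * b1 + b2 * b1 * a4 + a3 * a4 * b1;
    double x4 = b4 * b3 * b2 + a3 * a4 * a1 + b2 * a4 * a1 + b3 * b2 * a1;
    double s = x1 + x2 + x3 + x4;
    double E1 = x1 / s, E2 = x2 / s, E3 = x3 / s, E4 = x4 / s;
    double JnakNa = 3.0 * (E1 * a3 - E2 * b3);
    double JnakK = 2.0 * (E4 * b1 - E3 * a1);
    const double Pnak = 30.0;
    INaK = Pnak * (zna * JnakNa + zk * JnakK);
  }

  // minor background / pump currents
  double IKb = 0.003 * q[Q_xkb] * (v - EK);
  double INab = 3.75e-10 * q[Q_A1] * (nai * q[Q_e1v] - nao);
  double ICab = 2.5e-8 * q[Q_A2] * (cai * q[Q_e2v] - 0.341 * cao);
  double IpCa = 0.0005 * cai / (0.0005 + cai);

  // BacNav
  double e_bac = std::isnan(p[8]) ? ENa : p[8];
  double IBacNav = p[7] * mb * hb * (v - e_bac);

  double Itot = INa + INaL + Ito + ICaL + ICaNa + ICaK + IKr + IKs + IK1 +
                INaCa + INaK + IKb + INab + ICab + IpCa + IBacNav;

  if (cur) {
    cur[0] = INa; cur[1] = INaL; cur[2] = Ito;
    cur[3] = ICaL + ICaNa + ICaK;
    cur[4] = IKr; cur[5] = IKs; cur[6] = IK1;
    cur[7] = INaCa; cur[8] = INaK;
    cur[9] = IKb + INab + ICab + IpCa;
    cur[10] = IBacNav; cur[11] = Itot;
  }
  if (dt <= 0.0) return Itot;

  // ---- state updates (Rush-Larsen gates, forward-Euler concentrations) ----
  double hss = q[Q_hss];
  y[9] = q[Q_mss] + (m - q[Q_mss]) * q[Q_rl_m];
  y[10] = hss + (hf - hss) * q[Q_rl_hf];
  y[11] = hss + (hs - hss) * q[Q_rl_hs];
  y[12] = hss + (j - hss) * q[Q_rl_j];
  y[13] = q[Q_hssp] + (hsp - q[Q_hssp]) * q[Q_rl_hsp];
  y[14] = hss + (jp - hss) * q[Q_rl_jp];
  y[15] = q[Q_mLss] + (mL - q[Q_mLss]) * q[Q_rl_mL];
  y[16] = q[Q_hLss] + (hL - q[Q_hLss]) * lut.rl_hL;
  y[17] = q[Q_hLssp] + (hLp - q[Q_hLssp]) * lut.rl_hLp;
  y[18] = q[Q_ass] + (a - q[Q_ass]) * q[Q_rl_a];
  y[19] = q[Q_iss] + (iF - q[Q_iss]) * q[Q_rl_iF];
  y[20] = q[Q_iss] + (iS - q[Q_iss]) * q[Q_rl_iS];
  y[21] = q[Q_assp] + (ap - q[Q_assp]) * q[Q_rl_a];
  y[22] = q[Q_iss] + (iFp - q[Q_iss]) * q[Q_rl_iFp];
  y[23] = q[Q_iss] + (iSp - q[Q_iss]) * q[Q_rl_iSp];
  y[24] = q[Q_dss] + (d - q[Q_dss]) * q[Q_rl_d];
  double fss = q[Q_fss];
  y[25] = fss + (ff - fss) * q[Q_rl_ff];
  y[26] = fss + (fs - fss) * q[Q_rl_fs];
  y[27] = fss + (fcaf - fss) * q[Q_rl_fcaf];
  y[28] = fss + (fcas - fss) * q[Q_rl_fcas];
  y[29] = fss + (jca - fss) * lut.rl_jca;
  double nca_inf = anca * k2n / km2n;
  y[30] = nca_inf + (nca - nca_inf) * std::exp(-dt * km2n);
  y[31] = fss + (ffp - fss) * q[Q_rl_ffp];
  y[32] = fss + (fcafp - fss) * q[Q_rl_fcafp];
  y[33] = q[Q_xrss] + (xrf - q[Q_xrss]) * q[Q_rl_xrf];
  y[34] = q[Q_xrss] + (xrs - q[Q_xrss]) * q[Q_rl_xrs];
  y[35] = q[Q_xs1ss] + (xs1 - q[Q_xs1ss]) * q[Q_rl_xs1];
  y[36] = q[Q_xs1ss] + (xs2 - q[Q_xs1ss]) * q[Q_rl_xs2];
  y[37] = q[Q_xk1ss] + (xk1 - q[Q_xk1ss]) * q[Q_rl_xk1];
  y[41] = q[Q_mbss] + (mb - q[Q_mbss]) * q[Q_rl_mb];
  y[42] = q[Q_hbss] + (hb - q[Q_hbss]) * q[Q_rl_hb];

  // SR release (relaxation toward an ICaL- and JSR-load-dependent target)
  const double bt = 4.75;
  double l2 = (1.5 / cajsr) * (1.5 / cajsr);
  double l4 = l2 * l2;
  double load = 1.0 + l4 * l4;
  double Jrel_inf = 0.5 * bt * (-ICaL) / load;
  double tau_rel = bt / (1.0 + 0.0123 / cajsr);
  if (tau_rel < 0.001) tau_rel = 0.001;
  const double btp = 1.25 * bt;
  double Jrel_infp = 0.5 * btp * (-ICaL) / load;
  double tau_relp = btp / (1.0 + 0.0123 / cajsr);
  if (tau_relp < 0.001) tau_relp = 0.001;
  double Jrel = (1.0 - fphos) * Jrelnp + fphos * Jrelp;
  y[38] = Jrel_inf + (Jrelnp - Jrel_inf) * std::exp(-dt / tau_rel);
  y[39] = Jrel_infp + (Jrelp - Jrel_infp) * std::exp(-dt / tau_relp);

  // SERCA uptake, leak, translocation, diffusion between compartments
  double Jupnp = 0.004375 * cai / (cai + 0.00092);
  double Jupp = 2.75 * 0.004375 * cai / (cai + 0.00092 - 0.00017);
  double Jleak = 0.0039375 * cansr / 15.0;
  double Jup = (1.0 - fphos) * Jupnp + fphos * Jupp - Jleak;
  double Jtr = (cansr - cajsr) / 100.0;
  double JdiffNa = (nass - nai) / 2.0;
  double JdiffK = (kss - ki) / 2.0;
  double Jdiff = (cass - cai) / 0.2;

  y[40] = CaMKt + dt * (aCaMK * CaMKb * (CaMKb + CaMKt) - bCaMK * CaMKt);
  y[1] = nai + dt * (-(INa + INaL + 3.0 * INaCa_i + 3.0 * INaK + INab) *
                         Acap / (F * vmyo) +
                     JdiffNa * vss / vmyo);
  y[2] = nass + dt * (-(ICaNa + 3.0 * INaCa_ss) * Acap / (F * vss) - JdiffNa);
  y[3] = ki + dt * (-(Ito + IKr + IKs + IK1 + IKb - 2.0 * INaK) *
                        Acap / (F * vmyo) +
                    JdiffK * vss / vmyo);
  y[4] = kss + dt * (-ICaK * Acap / (F * vss) - JdiffK);
  const double cmdnmax = 0.05, kmcmdn = 0.00238, trpnmax = 0.07,
               kmtrpn = 0.0005;
  const double BSRmax = 0.047, KmBSR = 0.00087, BSLmax = 1.124,
               KmBSL = 0.0087;
  const double csqnmax = 10.0, kmcsqn = 0.8;
  double Bcai =
      1.0 / (1.0 + cmdnmax * kmcmdn / ((kmcmdn + cai) * (kmcmdn + cai)) +
             trpnmax * kmtrpn / ((kmtrpn + cai) * (kmtrpn + cai)));
  y[5] = cai + dt * Bcai *
                   (-(IpCa + ICab - 2.0 * INaCa_i) * Acap / (2.0 * F * vmyo) -
                    Jup * vnsr / vmyo + Jdiff * vss / vmyo);
  double Bcass =
      1.0 / (1.0 + BSRmax * KmBSR / ((KmBSR + cass) * (KmBSR + cass)) +
             BSLmax * KmBSL / ((KmBSL + cass) * (KmBSL + cass)));
  y[6] = cass + dt * Bcass *
                    (-(ICaL - 2.0 * INaCa_ss) * Acap / (2.0 * F * vss) +
                     Jrel * vjsr / vss - Jdiff);
  y[7] = cansr + dt * (Jup - Jtr * vjsr / vnsr);
  double Bcajsr =
      1.0 / (1.0 + csqnmax * kmcsqn / ((kmcsqn + cajsr) * (kmcsqn + cajsr)));
  y[8] = cajsr + dt * Bcajsr * (Jtr - Jrel);

  return Itot;
}

extern const Model ord_model;
const Model ord_model = {
  43, 9, 12, ord_states, ord_params, ord_currents,
  ord_init, ord_defaults, ord_step
};

}  // namespace bacnavsim
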