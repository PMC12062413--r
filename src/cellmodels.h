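// Core cell models: ten Tusscher-Panfilov 2006 (TP06) human ventricular
// myocyte (epicardial, shallow-restitution parameter set) and the MacCannell
// "active" fibroblast. All voltages in mV, time in ms, membrane currents in
// pA/pF, conductances in nS, capacitances in pF.
#pragma once
#include <cmath>
#include <vector>

namespace flk {

constexpr double R_GAS   = 8314.472;     // mJ mol^-1 K^-1
constexpr double FARADAY = 96485.3415;   // C mol^-1
constexpr double TEMP    = 310.0;        // K
constexpr double RTONF   = R_GAS * TEMP / FARADAY;  // mV
constexpr double FONRT   = 1.0 / RTONF;

// ---------------------------------------------------------------- TP06 -----

struct MyoParams {
  // maximal conductances, nS/pF (gcal in cm^3 uF^-1 s^-1)
  double gna  = 14.838;
  double gk1  = 5.405;
  double gto  = 0.294;     // epicardial
  double gkr  = 0.153;     // shallow-restitution set
  double gks  = 0.392;     // epicardial
  double gcal = 3.980e-5;
  double gbna = 2.9e-4;
  double gbca = 5.92e-4;
  double gpca = 0.1238;
  double gpk  = 0.0146;
  double p_nak  = 2.724;   // pA/pF
  double k_naca = 1000.0;  // pA/pF
  double tauf_scale = 2.0; // shallow restitution: f-gate time constant doubled
  double cm = 150.0;       // pF per myocyte grid unit
  double ko = 5.4, nao = 140.0, cao = 2.0;  // mM
};

// state layout
enum MyoIdx { MY_V = 0, MY_M, MY_H, MY_J, MY_XR1, MY_XR2, MY_XS, MY_R, MY_S,
              MY_D, MY_F, MY_F2, MY_FCASS, MY_CAI, MY_CASS, MY_CASR,
              MY_NAI, MY_KI, MY_RBAR, N_MYO };

struct MyoCurrents {
  double ina, ito, ik1, ikr, iks, ical, inaca, inak, ipca, ipk, ibca, ibna;
  double iion;
};

// fixed TP06 constants
constexpr double KM_K = 1.0, KM_NA = 40.0;
constexpr double KM_NAI = 87.5, KM_CA = 1.38, K_SAT = 0.1, GAM = 0.35;
constexpr double KP_CA = 0.0005;
constexpr double PK_NA = 0.03;
constexpr double V_C = 0.016404, V_SR = 0.001094, V_SS = 5.468e-5;
constexpr double BUF_C = 0.2,  K_BUF_C = 0.001;
constexpr double BUF_SR = 10., K_BUF_SR = 0.3;
constexpr double BUF_SS = 0.4, K_BUF_SS = 0.00025;
constexpr double VMAX_UP = 0.006375, K_UP = 0.00025;
constexpr double V_REL = 0.102, K1P = 0.15, K2P = 0.045, K3 = 0.060,
                 K4 = 0.005, EC_SR = 1.5, MAX_SR = 2.5, MIN_SR = 1.0;
constexpr double V_LEAK = 0.00036, V_XFER = 0.0038;
constexpr double CAPACITANCE = 0.185;

// voltage-dependent factors consumed by one forward-Euler step
struct MyoRates {
  double minf, mtau, hinf, htau, jinf, jtau;
  double xr1inf, xr1tau, xr2inf, xr2tau, xsinf, xstau;
  double rinf, rtau, sinf, stau, dinf, dtau, finf, ftau, f2inf, f2tau;
  double rec_inak, rec_ipk, e2v;      // e2v = exp(2 (V-15) F/RT)
  double expgv, expg1v;               // exp(gam V F/RT), exp((gam-1) V F/RT)
};

inline void myo_rates_exact(double v, double tauf_scale, MyoRates &rt) {
  rt.minf = 1. / ((1. + std::exp((-56.86 - v) / 9.03)) *
                  (1. + std::exp((-56.86 - v) / 9.03)));
  {
    double am = 1. / (1. + std::exp((-60. - v) / 5.));
    double bm = 0.1 / (1. + std::exp((v + 35.) / 5.)) +
                0.10 / (1. + std::exp((v - 50.) / 200.));
    rt.mtau = am * bm;
  }
  {
    double hi = 1. + std::exp((v + 71.55) / 7.43);
    rt.hinf = 1. / (hi * hi);
    rt.jinf = rt.hinf;
    double ah, bh, aj, bj;
    if (v >= -40.) {
      ah = 0.;
      bh = 0.77 / (0.13 * (1. + std::exp(-(v + 10.66) / 11.1)));
      aj = 0.;
      bj = 0.6 * std::exp(0.057 * v) / (1. + std::exp(-0.1 * (v + 32.)));
    } else {
      ah = 0.057 * std::exp(-(v + 80.) / 6.8);
      bh = 2.7 * std::exp(0.079 * v) + 3.1e5 * std::exp(0.3485 * v);
      aj = (-2.5428e4 * std::exp(0.2444 * v) -
            6.948e-6 * std::exp(-0.04391 * v)) *
           (v + 37.78) / (1. + std::exp(0.311 * (v + 79.23)));
      bj = 0.02424 * std::exp(-0.01052 * v) /
           (1. + std::exp(-0.1378 * (v + 40.14)));
    }
    rt.htau = 1. / (ah + bh);
    rt.jtau = 1. / (aj + bj);
  }
  rt.xr1inf = 1. / (1. + std::exp((-26. - v) / 7.));
  rt.xr1tau = (450. / (1. + std::exp((-45. - v) / 10.))) *
              (6. / (1. + std::exp((v + 30.) / 11.5)));
  rt.xr2inf = 1. / (1. + std::exp((v + 88.) / 24.));
  rt.xr2tau = (3. / (1. + std::exp((-60. - v) / 20.))) *
              (1.12 / (1. + std::exp((v - 60.) / 20.)));
  rt.xsinf = 1. / (1. + std::exp((-5. - v) / 14.));
  rt.xstau = (1400. / std::sqrt(1. + std::exp((5. - v) / 6.))) *
                 (1. / (1. + std::exp((v - 35.) / 15.))) + 80.;
  rt.rinf = 1. / (1. + std::exp((20. - v) / 6.));
  rt.rtau = 9.5 * std::exp(-(v + 40.) * (v + 40.) / 1800.) + 0.8;
  rt.sinf = 1. / (1. + std::exp((v + 20.) / 5.));
  rt.stau = 85. * std::exp(-(v + 45.) * (v + 45.) / 320.) +
            5. / (1. + std::exp((v - 20.) / 5.)) + 3.;
  rt.dinf = 1. / (1. + std::exp((-8. - v) / 7.5));
  {
    double ad = 1.4 / (1. + std::exp((-35. - v) / 13.)) + 0.25;
    double bd = 1.4 / (1. + std::exp((v + 5.) / 5.));
    double cd = 1. / (1. + std::exp((50. - v) / 20.));
    rt.dtau = ad * bd + cd;
  }
  rt.finf = 1. / (1. + std::exp((v + 20.) / 7.));
  {
    double af = 1102.5 * std::exp(-(v + 27.) * (v + 27.) / 225.);
    double bf = 200. / (1. + std::exp((13. - v) / 10.));
    double cf = 180. / (1. + std::exp((v + 30.) / 10.)) + 20.;
    rt.ftau = (af + bf + cf) * tauf_scale;
  }
  rt.f2inf = 0.67 / (1. + std::exp((v + 35.) / 7.)) + 0.33;
  {
    double af2 = 562. * std::exp(-(v + 27.) * (v + 27.) / 240.);
    double bf2 = 31. / (1. + std::exp((25. - v) / 10.));
    double cf2 = 80. / (1. + std::exp((v + 30.) / 10.));
    rt.f2tau = af2 + bf2 + cf2;
  }
  rt.rec_inak = 1. / (1. + 0.1245 * std::exp(-0.1 * v * FONRT) +
                      0.0353 * std::exp(-v * FONRT));
  rt.rec_ipk = 1. / (1. + std::exp((25. - v) / 5.98));
  rt.e2v = std::exp(2. * (v - 15.) * FONRT);
  rt.expgv = std::exp(GAM * v * FONRT);
  rt.expg1v = std::exp((GAM - 1.) * v * FONRT);
}

// IK1 open-probability rectification (function of V - EK)
inline double rec_ik1_exact(double vk) {
  double ak1 = 0.1 / (1. + std::exp(0.06 * (vk - 200.)));
  double bk1 = (3. * std::exp(0.0002 * (vk + 100.)) +
                std::exp(0.1 * (vk - 10.))) /
               (1. + std::exp(-0.5 * vk));
  return ak1 / (ak1 + bk1);
}

// Exponential (Rush-Larsen) gate factors exp(-dt/tau) for a fixed dt.
struct GateExp {
  double em, eh, ej, exr1, exr2, exs, er, es, ed, ef, ef2;
};

inline void gate_exp_from(const MyoRates &rt, double dt, GateExp &g) {
  g.em = std::exp(-dt / rt.mtau);   g.eh = std::exp(-dt / rt.htau);
  g.ej = std::exp(-dt / rt.jtau);   g.exr1 = std::exp(-dt / rt.xr1tau);
  g.exr2 = std::exp(-dt / rt.xr2tau); g.exs = std::exp(-dt / rt.xstau);
  g.er = std::exp(-dt / rt.rtau);   g.es = std::exp(-dt / rt.stau);
  g.ed = std::exp(-dt / rt.dtau);   g.ef = std::exp(-dt / rt.ftau);
  g.ef2 = std::exp(-dt / rt.f2tau);
}

// Lookup tables over V for the tissue solver (the standard speedup for
// lattice monodomain codes). Linear interpolation; 0.02 mV resolution.
// Gate update factors exp(-dt/tau) are tabulated for the solver's dt.
struct Tp06Tables {
  static constexpr double VMIN = -120.0, VMAX = 80.0;
  static constexpr int NV = 10001;
  static constexpr double VKMIN = -160.0, VKMAX = 280.0;
  static constexpr int NVK = 11001;
  double dv, invdv, dvk, invdvk;
  std::vector<MyoRates> rates;     // indexed by V
  std::vector<GateExp> gexp;       // indexed by V, for time step dt
  std::vector<double> ik1rec;      // indexed by V - EK
  double tauf_scale, dt;

  Tp06Tables(double tauf_scale_, double dt_)
      : tauf_scale(tauf_scale_), dt(dt_) {
    dv = (VMAX - VMIN) / (NV - 1); invdv = 1.0 / dv;
    dvk = (VKMAX - VKMIN) / (NVK - 1); invdvk = 1.0 / dvk;
    rates.resize(NV);
    gexp.resize(NV);
    for (int k = 0; k < NV; ++k) {
      myo_rates_exact(VMIN + k * dv, tauf_scale, rates[k]);
      gate_exp_from(rates[k], dt, gexp[k]);
    }
    ik1rec.resize(NVK);
    for (int k = 0; k < NVK; ++k)
      ik1rec[k] = rec_ik1_exact(VKMIN + k * dvk);
  }

  inline void lookup(double v, MyoRates &out, GateExp &gout) const {
    double u = (v - VMIN) * invdv;
    int k = (int)u;
    if (k < 0) { k = 0; u = 0; }
    if (k > NV - 2) { k = NV - 2; u = NV - 1; }
    double w = u - k;
    {
      const double *pa = reinterpret_cast<const double *>(&rates[k]);
      const double *pb = reinterpret_cast<const double *>(&rates[k + 1]);
      double *po = reinterpret_cast<double *>(&out);
      constexpr int nf = sizeof(MyoRates) / sizeof(double);
      for (int f = 0; f < nf; ++f) po[f] = pa[f] + w * (pb[f] - pa[f]);
    }
    {
      const double *pa = reinterpret_cast<const double *>(&gexp[k]);
      const double *pb = reinterpret_cast<const double *>(&gexp[k + 1]);
      double *po = reinterpret_cast<double *>(&gout);
      constexpr int nf = sizeof(GateExp) / sizeof(double);
      for (int f = 0; f < nf; ++f) po[f] = pa[f] + w * (pb[f] - pa[f]);
    }
  }

  inline double ik1(double vk) const {
    double u = (vk - VKMIN) * invdvk;
    int k = (int)u;
    if (k < 0) { k = 0; u = 0; }
    if (k > NVK - 2) { k = NVK - 2; u = NVK - 1; }
    double w = u - k;
    return ik1rec[k] + w * (ik1rec[k + 1] - ik1rec[k]);
  }
};

// currents at the given state (pA/pF, outward positive)
inline void myo_currents(const double *y, const MyoParams &P,
                         const MyoRates &rt, double rec_ik1,
                         MyoCurrents &c) {
  double v = y[MY_V];
  double ek = RTONF * std::log(P.ko / y[MY_KI]);
  double ena = RTONF * std::log(P.nao / y[MY_NAI]);
  double eks = RTONF * std::log((P.ko + PK_NA * P.nao) /
                                (y[MY_KI] + PK_NA * y[MY_NAI]));
  double eca = 0.5 * RTONF * std::log(P.cao / y[MY_CAI]);

  c.ina = P.gna * y[MY_M] * y[MY_M] * y[MY_M] * y[MY_H] * y[MY_J] * (v - ena);
  c.ito = P.gto * y[MY_R] * y[MY_S] * (v - ek);
  c.ik1 = P.gk1 * rec_ik1 * (v - ek);
  c.ikr = P.gkr * std::sqrt(P.ko / 5.4) * y[MY_XR1] * y[MY_XR2] * (v - ek);
  c.iks = P.gks * y[MY_XS] * y[MY_XS] * (v - eks);
  {
    double vh = v - 15.;
    double gate = y[MY_D] * y[MY_F] * y[MY_F2] * y[MY_FCASS];
    double den = rt.e2v - 1.;
    double frac;
    if (std::fabs(vh) < 1e-5) {
      // limit of vh/(e2v - 1) as vh -> 0
      frac = (0.25 * y[MY_CASS] - P.cao) / (2. * FONRT);
    } else {
      frac = vh * (0.25 * rt.e2v * y[MY_CASS] - P.cao) / den;
    }
    c.ical = P.gcal * gate * 4. * FARADAY * FONRT * frac;
  }
  {
    double nai3 = y[MY_NAI] * y[MY_NAI] * y[MY_NAI];
    double nao3 = P.nao * P.nao * P.nao;
    c.inaca = P.k_naca * (1. / (KM_NAI * KM_NAI * KM_NAI + nao3)) *
              (1. / (KM_CA + P.cao)) * (1. / (1. + K_SAT * rt.expg1v)) *
              (rt.expgv * nai3 * P.cao - rt.expg1v * nao3 * y[MY_CAI] * 2.5);
  }
  c.inak = P.p_nak * (P.ko / (P.ko + KM_K)) *
           (y[MY_NAI] / (y[MY_NAI] + KM_NA)) * rt.rec_inak;
  c.ipca = P.gpca * y[MY_CAI] / (KP_CA + y[MY_CAI]);
  c.ipk = P.gpk * rt.rec_ipk * (v - ek);
  c.ibna = P.gbna * (v - ena);
  c.ibca = P.gbca * (v - eca);
  c.iion = c.ina + c.ito + c.ik1 + c.ikr + c.iks + c.ical + c.inaca +
           c.inak + c.ipca + c.ipk + c.ibca + c.ibna;
}

inline void myo_currents_exact(const double *y, const MyoParams &P,
                               MyoCurrents &c) {
  MyoRates rt;
  myo_rates_exact(y[MY_V], P.tauf_scale, rt);
  double ek = RTONF * std::log(P.ko / y[MY_KI]);
  myo_currents(y, P, rt, rec_ik1_exact(y[MY_V] - ek), c);
}

// One forward-Euler step. istim and the M-F coupling term enter dV/dt as
// pA/pF; dvdt_diff is the diffusion contribution in mV/ms. Gate update is
// forward Euler by default, Rush-Larsen when rl = true. Returns I_ion.
inline double myo_step(double *y, const MyoParams &P, const Tp06Tables *tb,
                       double dt, double istim, double couple_pApF,
                       double dvdt_diff, bool rl) {
  MyoRates rt;
  GateExp ge;
  double v = y[MY_V];
  double ek = RTONF * std::log(P.ko / y[MY_KI]);
  double ik1rec;
  if (tb) {
    tb->lookup(v, rt, ge);
    ik1rec = tb->ik1(v - ek);
  } else {
    myo_rates_exact(v, P.tauf_scale, rt);
    if (rl) gate_exp_from(rt, dt, ge);
    ik1rec = rec_ik1_exact(v - ek);
  }
  MyoCurrents c;
  myo_currents(y, P, rt, ik1rec, c);

  // Ca subsystem (analytic buffering update, as in the TP06 reference code)
  double cai = y[MY_CAI], cass = y[MY_CASS], casr = y[MY_CASR];
  double kcasr = MAX_SR - (MAX_SR - MIN_SR) /
                              (1. + (EC_SR / casr) * (EC_SR / casr));
  double k1 = K1P / kcasr;
  double k2 = K2P * kcasr;
  double rbar = y[MY_RBAR];
  y[MY_RBAR] += dt * (K4 * (1. - rbar) - k2 * cass * rbar);
  double oo = k1 * cass * cass * rbar / (K3 + k1 * cass * cass);
  double irel = V_REL * oo * (casr - cass);
  double ileak = V_LEAK * (casr - cai);
  double iup = VMAX_UP / (1. + K_UP * K_UP / (cai * cai));
  double ixfer = V_XFER * (cass - cai);

  {
    double casqn = BUF_SR * casr / (casr + K_BUF_SR);
    double d = dt * (iup - irel - ileak);
    double b = BUF_SR - casqn - d - casr + K_BUF_SR;
    double cc = K_BUF_SR * (casqn + d + casr);
    y[MY_CASR] = (std::sqrt(b * b + 4. * cc) - b) / 2.;
  }
  {
    double cbuf = BUF_SS * cass / (cass + K_BUF_SS);
    double d = dt * (-ixfer * (V_C / V_SS) + irel * (V_SR / V_SS) +
                     (-c.ical * (1. / (2. * V_SS * FARADAY)) * CAPACITANCE));
    double b = BUF_SS - cbuf - d - cass + K_BUF_SS;
    double cc = K_BUF_SS * (cbuf + d + cass);
    y[MY_CASS] = (std::sqrt(b * b + 4. * cc) - b) / 2.;
  }
  {
    double cbuf = BUF_C * cai / (cai + K_BUF_C);
    double d = dt * ((-(c.ibca + c.ipca - 2. * c.inaca) *
                      (1. / (2. * V_C * FARADAY)) * CAPACITANCE) -
                     (iup - ileak) * (V_SR / V_C) + ixfer);
    double b = BUF_C - cbuf - d - cai + K_BUF_C;
    double cc = K_BUF_C * (cbuf + d + cai);
    y[MY_CAI] = (std::sqrt(b * b + 4. * cc) - b) / 2.;
  }
  y[MY_NAI] += dt * (-(c.ina + c.ibna + 3. * c.inak + 3. * c.inaca) *
                     (1. / (V_C * FARADAY)) * CAPACITANCE);
  y[MY_KI] += dt * (-(istim + c.ik1 + c.ito + c.ikr + c.iks - 2. * c.inak +
                      c.ipk) * (1. / (V_C * FARADAY)) * CAPACITANCE);

  // gates
  double fcassinf = 0.6 / (1. + (cass / 0.05) * (cass / 0.05)) + 0.4;
  double fcasstau = 80. / (1. + (cass / 0.05) * (cass / 0.05)) + 2.;
  if (rl) {
    // tabulated factors are built for the table dt; direct path computes them
    y[MY_M] = rt.minf - (rt.minf - y[MY_M]) * ge.em;
    y[MY_H] = rt.hinf - (rt.hinf - y[MY_H]) * ge.eh;
    y[MY_J] = rt.jinf - (rt.jinf - y[MY_J]) * ge.ej;
    y[MY_XR1] = rt.xr1inf - (rt.xr1inf - y[MY_XR1]) * ge.exr1;
    y[MY_XR2] = rt.xr2inf - (rt.xr2inf - y[MY_XR2]) * ge.exr2;
    y[MY_XS] = rt.xsinf - (rt.xsinf - y[MY_XS]) * ge.exs;
    y[MY_R] = rt.rinf - (rt.rinf - y[MY_R]) * ge.er;
    y[MY_S] = rt.sinf - (rt.sinf - y[MY_S]) * ge.es;
    y[MY_D] = rt.dinf - (rt.dinf - y[MY_D]) * ge.ed;
    y[MY_F] = rt.finf - (rt.finf - y[MY_F]) * ge.ef;
    y[MY_F2] = rt.f2inf - (rt.f2inf - y[MY_F2]) * ge.ef2;
    y[MY_FCASS] = fcassinf - (fcassinf - y[MY_FCASS]) * std::exp(-dt / fcasstau);
  } else {
    y[MY_M] += dt * (rt.minf - y[MY_M]) / rt.mtau;
    y[MY_H] += dt * (rt.hinf - y[MY_H]) / rt.htau;
    y[MY_J] += dt * (rt.jinf - y[MY_J]) / rt.jtau;
    y[MY_XR1] += dt * (rt.xr1inf - y[MY_XR1]) / rt.xr1tau;
    y[MY_XR2] += dt * (rt.xr2inf - y[MY_XR2]) / rt.xr2tau;
    y[MY_XS] += dt * (rt.xsinf - y[MY_XS]) / rt.xstau;
    y[MY_R] += dt * (rt.rinf - y[MY_R]) / rt.rtau;
    y[MY_S] += dt * (rt.sinf - y[MY_S]) / rt.stau;
    y[MY_D] += dt * (rt.dinf - y[MY_D]) / rt.dtau;
    y[MY_F] += dt * (rt.finf - y[MY_F]) / rt.ftau;
    y[MY_F2] += dt * (rt.f2inf - y[MY_F2]) / rt.f2tau;
    y[MY_FCASS] += dt * (fcassinf - y[MY_FCASS]) / fcasstau;
  }

  y[MY_V] += dt * (-(c.iion + istim) + couple_pApF + dvdt_diff);
  return c.iion;
}

inline void myo_initial(double *y) {
  y[MY_V] = -86.2;
  y[MY_M] = 0.0;   y[MY_H] = 0.75; y[MY_J] = 0.75;
  y[MY_XR1] = 0.0; y[MY_XR2] = 1.0; y[MY_XS] = 0.0;
  y[MY_R] = 0.0;   y[MY_S] = 1.0;
  y[MY_D] = 0.0;   y[MY_F] = 1.0;  y[MY_F2] = 1.0; y[MY_FCASS] = 1.0;
  y[MY_CAI] = 7e-5; y[MY_CASS] = 7e-5; y[MY_CASR] = 1.3;
  y[MY_NAI] = 7.67; y[MY_KI] = 138.3; y[MY_RBAR] = 1.0;
}

// ----------------------------------------------------- MacCannell ---------

struct FibParams {
  double cf = 50.0;        // pF per fibroblast (myofibroblast scale)
  double nf = 8.0;         // fibroblasts in parallel per unit
  double gkv = 0.25;       // nS/pF
  double gk1 = 0.4822;     // nS/pF
  double gbna = 0.0095;    // nS/pF
  double inak_max = 2.002; // pA/pF
  double kmk = 1.0, kmna = 11.0;       // mM
  double vrev = -150.0;    // mV
  double ki = 129.4349, nai = 8.5547;  // mM, fixed
  double ko = 5.3581, nao = 130.0110;  // mM
  double kv_shift = 0.0;   // mV shift of the Kv gating voltage dependence
};

enum FibIdx { FB_V = 0, FB_R, FB_S, N_FIB };

struct FibCurrents { double ikv, ik1, inak, ibna, iion; };

inline void fib_currents(const double *y, const FibParams &P,
                         FibCurrents &c) {
  double v = y[FB_V];
  double ek = RTONF * std::log(P.ko / P.ki);
  double ena = RTONF * std::log(P.nao / P.nai);
  c.ikv = P.gkv * y[FB_R] * y[FB_S] * (v - ek);
  c.ik1 = P.gk1 * rec_ik1_exact(v - ek) * (v - ek);
  double nai15 = std::pow(P.nai, 1.5), kmna15 = std::pow(P.kmna, 1.5);
  c.inak = P.inak_max * (P.ko / (P.ko + P.kmk)) *
           (nai15 / (nai15 + kmna15)) * (v - P.vrev) / (v + 200.0);
  c.ibna = P.gbna * (v - ena);
  c.iion = c.ikv + c.ik1 + c.inak + c.ibna;
}

inline void fib_gate_rates(double v, const FibParams &P, double &rinf,
                           double &rtau, double &sinf, double &stau) {
  double u = v - P.kv_shift;
  rinf = 1. / (1. + std::exp(-(u + 20.) / 11.));
  rtau = 20.3 + 138. * std::exp(-((u + 20.) / 25.9) * ((u + 20.) / 25.9));
  sinf = 1. / (1. + std::exp((u + 23.) / 2.7));
  stau = 1574. + 5268. * std::exp(-((u + 23.) / 22.7) * ((u + 23.) / 22.7));
}

// couple_pA: total gap-junctional current into ONE fibroblast of the unit,
// i.e. sum over attached grid points of Gs (V - Vf), in pA.
inline double fib_step(double *y, const FibParams &P, double dt,
                       double couple_pA, bool rl, bool freeze_ion) {
  FibCurrents c;
  double iion = 0.0;
  if (!freeze_ion) {
    fib_currents(y, P, c);
    iion = c.iion;
  }
  double rinf, rtau, sinf, stau;
  fib_gate_rates(y[FB_V], P, rinf, rtau, sinf, stau);
  if (rl) {
    y[FB_R] = rinf - (rinf - y[FB_R]) * std::exp(-dt / rtau);
    y[FB_S] = sinf - (sinf - y[FB_S]) * std::exp(-dt / stau);
  } else {
    y[FB_R] += dt * (rinf - y[FB_R]) / rtau;
    y[FB_S] += dt * (sinf - y[FB_S]) / stau;
  }
  y[FB_V] += dt * (-iion + couple_pA / P.cf);
  return iion;
}

inline void fib_initial(double *y, const FibParams &P, double v0) {
  double rinf, rtau, sinf, stau;
  fib_gate_rates(v0, P, rinf, rtau, sinf, stau);
  y[FB_V] = v0; y[FB_R] = rinf; y[FB_S] = sinf;
}

}  // namespace flk
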