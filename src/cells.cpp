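// Single-cell (0D) drivers: current breakdowns, quiescent/paced integration
// of the TP06 myocyte, the MacCannell fibroblast unit, and a myocyte coupled
// to one fibroblast unit via a Gs gap junction.
#include <Rcpp.h>
#include <memory>
#include "cellmodels.h"
using namespace Rcpp;
using namespace flk;

static MyoParams parse_myo(const List &p) {
  MyoParams P;
  P.gna = p["gna"]; P.gk1 = p["gk1"]; P.gto = p["gto"];
  P.gkr = p["gkr"]; P.gks = p["gks"]; P.gcal = p["gcal"];
  P.gbna = p["gbna"]; P.gbca = p["gbca"]; P.gpca = p["gpca"];
  P.gpk = p["gpk"]; P.p_nak = p["p_nak"]; P.k_naca = p["k_naca"];
  P.tauf_scale = p["tauf_scale"]; P.cm = p["cm"];
  P.ko = p["ko"]; P.nao = p["nao"]; P.cao = p["cao"];
  return P;
}

static FibParams parse_fib(const List &p) {
  FibParams P;
  P.cf = p["cf"]; P.nf = p["nf"]; P.gkv = p["gkv"]; P.gk1 = p["gk1"];
  P.gbna = p["gbna"]; P.inak_max = p["inak_max"]; P.kmk = p["kmk"];
  P.kmna = p["kmna"]; P.vrev = p["vrev"]; P.ki = p["ki"]; P.nai = p["nai"];
  P.ko = p["ko"]; P.nao = p["nao"]; P.kv_shift = p["kv_shift"];
  return P;
}

static void check_state(const NumericVector &y, int n, const char *what) {
  if (y.size() != n)
    stop("%s state must have %d elements, got %d", what, n, (int)y.size());
  CharacterVector nm = y.names();
  for (int i = 0; i < n; ++i)
    if (!R_finite(y[i]))
      stop("non-finite %s state variable '%s' (index %d)", what,
           nm.size() == n ? as<std::string>(nm[i]).c_str() : "?", i + 1);
}

// [[Rcpp::export]]
List cpp_myocyte_currents(NumericVector state, List params) {
  check_state(state, N_MYO, "myocyte");
  MyoParams P = parse_myo(params);
  MyoCurrents c;
  myo_currents_exact(&state[0], P, c);
  return List::create(
      _["i_na"] = c.ina, _["i_to"] = c.ito, _["i_k1"] = c.ik1,
      _["i_kr"] = c.ikr, _["i_ks"] = c.iks, _["i_cal"] = c.ical,
      _["i_naca"] = c.inaca, _["i_nak"] = c.inak, _["i_pca"] = c.ipca,
      _["i_pk"] = c.ipk, _["i_bca"] = c.ibca, _["i_bna"] = c.ibna,
      _["i_ion"] = c.iion);
}

// [[Rcpp::export]]
List cpp_fibroblast_currents(NumericVector state, List params) {
  check_state(state, N_FIB, "fibroblast");
  FibParams P = parse_fib(params);
  FibCurrents c;
  fib_currents(&state[0], P, c);
  return List::create(_["i_kv"] = c.ikv, _["i_k1"] = c.ik1,
                      _["i_nak"] = c.inak, _["i_bna"] = c.ibna,
                      _["i_ion"] = c.iion);
}

// [[Rcpp::export]]
NumericVector cpp_myocyte_initial() {
  NumericVector y(N_MYO);
  myo_initial(&y[0]);
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_fibroblast_initial(List params, double v0) {
  FibParams P = parse_fib(params);
  NumericVector y(N_FIB);
  fib_initial(&y[0], P, v0);
  return y;
}

// Paced 0D run: myocyte, optionally coupled to one fibroblast unit of
// P.nf parallel fibroblasts through a junction of gs nS per fibroblast.
// stim_times are stimulus onsets (ms); stim_amp in pA/pF (negative =
// depolarizing, TP06 convention).
// [[Rcpp::export]]
List cpp_run_cell(NumericVector myo_state, List myo_params,
                  Nullable<NumericVector> fib_state, List fib_params,
                  double gs, double duration, double dt,
                  NumericVector stim_times, double stim_dur, double stim_amp,
                  double record_dt, bool record_states, bool rush_larsen,
                  bool use_tables) {
  check_state(myo_state, N_MYO, "myocyte");
  MyoParams P = parse_myo(myo_params);
  FibParams FP = parse_fib(fib_params);
  if (gs < 0) stop("gs must be non-negative");
  bool with_fib = fib_state.isNotNull();
  double yf[N_FIB] = {0, 0, 0};
  if (with_fib) {
    NumericVector f(fib_state);
    check_state(f, N_FIB, "fibroblast");
    for (int i = 0; i < N_FIB; ++i) yf[i] = f[i];
  }
  std::vector<double> y(myo_state.begin(), myo_state.end());

  Tp06Tables *tb = nullptr;
  std::unique_ptr<Tp06Tables> tb_own;
  if (use_tables) {
    tb_own.reset(new Tp06Tables(P.tauf_scale, dt));
    tb = tb_own.get();
  }

  long nsteps = (long)std::llround(duration / dt);
  int rec_stride = std::max(1, (int)std::llround(record_dt / dt));
  long nrec = nsteps / rec_stride + 1;
  NumericVector out_t(nrec), out_v(nrec), out_vf(nrec);
  NumericMatrix out_states(record_states ? nrec : 1, N_MYO);
  long ns = 0, nstim = stim_times.size();

  auto record = [&](long k, double t) {
    out_t[k] = t; out_v[k] = y[MY_V];
    out_vf[k] = with_fib ? yf[FB_V] : NA_REAL;
    if (record_states)
      for (int v = 0; v < N_MYO; ++v) out_states(k, v) = y[v];
  };
  record(0, 0.0);

  long krec = 1;
  int sptr = 0;
  for (long s = 0; s < nsteps; ++s) {
    double t = s * dt;
    while (sptr < nstim && t >= stim_times[sptr] + stim_dur) ++sptr;
    double istim =
        (sptr < nstim && t >= stim_times[sptr] && t < stim_times[sptr] + stim_dur)
            ? stim_amp : 0.0;
    double couple = 0.0, fcouple = 0.0;
    if (with_fib) {
      couple = FP.nf * gs * (yf[FB_V] - y[MY_V]) / P.cm;  // pA/pF
      fcouple = gs * (y[MY_V] - yf[FB_V]);                // pA per fibroblast
    }
    myo_step(&y[0], P, tb, dt, istim, couple, 0.0, rush_larsen);
    if (with_fib) fib_step(yf, FP, dt, fcouple, rush_larsen, false);
    if (!(y[MY_V] > -200.0 && y[MY_V] < 200.0))
      stop("myocyte integration unstable at t = %.2f ms (V = %g)", t, y[MY_V]);
    if ((s + 1) % rec_stride == 0 && krec < nrec) record(krec++, (s + 1) * dt);
    if ((s & 0xFFFFF) == 0) checkUserInterrupt();
  }
  (void)ns;

  NumericVector fin(y.begin(), y.end());
  NumericVector finf(yf, yf + N_FIB);
  return List::create(_["time"] = out_t, _["v"] = out_v, _["vf"] = out_vf,
                      _["states"] = record_states ? (SEXP)out_states : R_NilValue,
                      _["final_myo"] = fin,
                      _["final_fib"] = with_fib ? (SEXP)finf : R_NilValue);
}

// Uncoupled fibroblast unit integration (quiescent).
// [[Rcpp::export]]
List cpp_run_fibroblast(NumericVector fib_state, List fib_params,
                        double duration, double dt, double record_dt) {
  check_state(fib_state, N_FIB, "fibroblast");
  FibParams P = parse_fib(fib_params);
  double y[N_FIB];
  for (int i = 0; i < N_FIB; ++i) y[i] = fib_state[i];
  long nsteps = (long)std::llround(duration / dt);
  int rec_stride = std::max(1, (int)std::llround(record_dt / dt));
  long nrec = nsteps / rec_stride + 1;
  NumericVector out_t(nrec), out_v(nrec), out_r(nrec), out_s(nrec);
  out_t[0] = 0; out_v[0] = y[FB_V]; out_r[0] = y[FB_R]; out_s[0] = y[FB_S];
  long krec = 1;
  for (long s = 0; s < nsteps; ++s) {
    fib_step(y, P, dt, 0.0, false, false);
    if (!(y[FB_V] > -200.0 && y[FB_V] < 200.0))
      stop("fibroblast integration unstable at t = %.2f ms", s * dt);
    if ((s + 1) % rec_stride == 0 && krec < nrec) {
      out_t[krec] = (s + 1) * dt; out_v[krec] = y[FB_V];
      out_r[krec] = y[FB_R]; out_s[krec] = y[FB_S];
      ++krec;
    }
    if ((s & 0xFFFFF) == 0) checkUserInterrupt();
  }
  return List::create(_["time"] = out_t, _["vf"] = out_v, _["r"] = out_r,
                      _["s"] = out_s,
                      _["final_fib"] = NumericVector(y, y + N_FIB));
}
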