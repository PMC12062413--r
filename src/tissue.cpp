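// 2D monodomain solver: forward-Euler integration of the myocyte field
// (ionic currents + flux-conservative five-point diffusion + M-F coupling +
// stimulus) and of the fibroblast units (ionic + coupling). No-flux
// boundaries at the domain edges and at every scar face (face diffusivity
// zero when either neighbour is scar).
#include <Rcpp.h>
#include <memory>
#include "cellmodels.h"
using namespace Rcpp;
using namespace flk;

static MyoParams parse_myo2(const List &p) {
  MyoParams P;
  P.gna = p["gna"]; P.gk1 = p["gk1"]; P.gto = p["gto"];
  P.gkr = p["gkr"]; P.gks = p["gks"]; P.gcal = p["gcal"];
  P.gbna = p["gbna"]; P.gbca = p["gbca"]; P.gpca = p["gpca"];
  P.gpk = p["gpk"]; P.p_nak = p["p_nak"]; P.k_naca = p["k_naca"];
  P.tauf_scale = p["tauf_scale"]; P.cm = p["cm"];
  P.ko = p["ko"]; P.nao = p["nao"]; P.cao = p["cao"];
  return P;
}

static FibParams parse_fib2(const List &p) {
  FibParams P;
  P.cf = p["cf"]; P.nf = p["nf"]; P.gkv = p["gkv"]; P.gk1 = p["gk1"];
  P.gbna = p["gbna"]; P.inak_max = p["inak_max"]; P.kmk = p["kmk"];
  P.kmna = p["kmna"]; P.vrev = p["vrev"]; P.ki = p["ki"]; P.nai = p["nai"];
  P.ko = p["ko"]; P.nao = p["nao"]; P.kv_shift = p["kv_shift"];
  return P;
}

// All indices at this boundary are 0-based. Point p maps to lattice site
// (i, j) with p = i + nx * j, matching an R matrix V[nx, ny] column-major.
// [[Rcpp::export]]
List cpp_run_tissue(int nx, int ny, IntegerVector scar, double d_mm2,
                    double dx, List myo_params, List fib_params,
                    NumericMatrix myo0, NumericMatrix fib0,
                    IntegerVector unit_ptr, IntegerVector unit_pts,
                    double gs, bool inactive_scar, double t0, double dt,
                    int nsteps, NumericVector stim_times, double stim_dur,
                    double stim_amp, IntegerVector stim_idx,
                    IntegerVector line_idx, int line_stride, int snap_stride,
                    double act_thresh, double act_lockout, int max_act,
                    IntegerVector exit_idx, bool record_fib,
                    bool freeze_myo_ion, bool freeze_fib_ion,
                    bool rush_larsen) {
  const int npts = nx * ny;
  if (scar.size() != npts) stop("scar mask size mismatch");
  if (myo0.nrow() != npts || myo0.ncol() != N_MYO)
    stop("myocyte state matrix must be %d x %d", npts, N_MYO);
  const int nunits = fib0.nrow();
  if (nunits > 0 && fib0.ncol() != N_FIB)
    stop("fibroblast state matrix must have %d columns", N_FIB);
  if (unit_ptr.size() != nunits + 1) stop("unit_ptr size mismatch");
  if (gs < 0) stop("gs must be non-negative");
  MyoParams P = parse_myo2(myo_params);
  FibParams FP = parse_fib2(fib_params);
  const double nfgs = FP.nf * gs;  // effective unit->point conductance, nS

  // state arrays (column-major copies; V duplicated for the update sweep)
  std::vector<double> Y(myo0.begin(), myo0.end());  // npts x N_MYO
  auto ycol = [&](int v) { return Y.data() + (size_t)v * npts; };
  std::vector<double> Vold(ycol(MY_V), ycol(MY_V) + npts);
  std::vector<double> Fy(fib0.begin(), fib0.end());
  auto fcol = [&](int v) { return Fy.data() + (size_t)v * nunits; };

  // face diffusivities (0 across scar faces and beyond domain edges)
  std::vector<double> fx((size_t)npts, 0.0), fy_((size_t)npts, 0.0);
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      int p = i + nx * j;
      if (i < nx - 1 && !scar[p] && !scar[p + 1]) fx[p] = d_mm2;
      if (j < ny - 1 && !scar[p] && !scar[p + nx]) fy_[p] = d_mm2;
    }
  const double invdx2 = 1.0 / (dx * dx);

  // invert the unit->points map for the myocyte-side coupling sum
  const int nlinks = unit_pts.size();
  std::vector<int> pt_cnt(npts, 0);
  for (int l = 0; l < nlinks; ++l) {
    if (unit_pts[l] < 0 || unit_pts[l] >= npts) stop("link point out of range");
    ++pt_cnt[unit_pts[l]];
  }
  std::vector<int> pt_ptr(npts + 1, 0);
  for (int p = 0; p < npts; ++p) pt_ptr[p + 1] = pt_ptr[p] + pt_cnt[p];
  std::vector<int> pt_unit(nlinks);
  {
    std::vector<int> cur(pt_ptr.begin(), pt_ptr.end() - 1);
    for (int u = 0; u < nunits; ++u)
      for (int l = unit_ptr[u]; l < unit_ptr[u + 1]; ++l)
        pt_unit[cur[unit_pts[l]]++] = u;
  }
  std::vector<int> linked_pts;
  for (int p = 0; p < npts; ++p)
    if (pt_cnt[p] > 0) linked_pts.push_back(p);
  std::vector<double> couple_m(npts, 0.0);  // pA into each linked point

  // stimulus mask
  std::vector<char> stim_mask(npts, 0);
  for (int k = 0; k < stim_idx.size(); ++k) stim_mask[stim_idx[k]] = 1;

  // recording buffers
  const int nline = line_idx.size();
  const long nlrec = line_stride > 0 ? (long)nsteps / line_stride + 1 : 0;
  NumericMatrix line_v(std::max(nlrec, 1L), std::max(nline, 1));
  NumericVector line_t(std::max(nlrec, 1L));
  const long nsnap = snap_stride > 0 ? (long)nsteps / snap_stride + 1 : 0;
  NumericVector snaps((size_t)std::max(nsnap, 0L) * npts);
  NumericVector snap_t(std::max(nsnap, 1L));
  const long nfrec = record_fib && line_stride > 0 ? nlrec : 0;
  NumericMatrix fib_v(std::max(nfrec, 1L), std::max(nunits, 1));

  NumericMatrix act(npts, max_act);
  std::fill(act.begin(), act.end(), NA_REAL);
  IntegerVector n_act(npts, 0);
  std::vector<double> last_act(npts, -1e18);
  std::vector<char> is_exit(npts, 0);
  for (int k = 0; k < exit_idx.size(); ++k) is_exit[exit_idx[k]] = 1;
  bool want_exit = exit_idx.size() > 0;

  Tp06Tables tables(P.tauf_scale, dt);
  double balance_max = 0.0, stop_time = NA_REAL;

  auto rec_line = [&](long k, double t) {
    line_t[k] = t;
    for (int c = 0; c < nline; ++c) line_v(k, c) = ycol(MY_V)[line_idx[c]];
    if (record_fib && k < std::max(nfrec, 1L))
      for (int u = 0; u < nunits; ++u) fib_v(k, u) = fcol(FB_V)[u];
  };
  auto rec_snap = [&](long k, double t) {
    snap_t[k] = t;
    std::copy(ycol(MY_V), ycol(MY_V) + npts, snaps.begin() + (size_t)k * npts);
  };
  if (nlrec > 0) rec_line(0, t0);
  if (nsnap > 0) rec_snap(0, t0);

  int sptr = 0;
  const int nstim = stim_times.size();
  long klrec = 1, ksnap = 1;
  bool stopped = false;

  for (int s = 0; s < nsteps && !stopped; ++s) {
    double t = t0 + s * dt;
    while (sptr < nstim && t >= stim_times[sptr] + stim_dur) ++sptr;
    bool stim_on =
        sptr < nstim && t >= stim_times[sptr] && t < stim_times[sptr] + stim_dur;

    // M-F coupling, both sides computed from the same pre-step voltages
    double tot_m = 0.0, tot_f = 0.0;
    for (int idx = (int)linked_pts.size(); idx-- > 0;) {
      int p = linked_pts[idx];
      double c = 0.0, v = Vold[p];
      for (int l = pt_ptr[p]; l < pt_ptr[p + 1]; ++l)
        c += nfgs * (fcol(FB_V)[pt_unit[l]] - v);
      couple_m[p] = c;
      tot_m += c;
    }

    // myocyte field update
    for (int j = 0; j < ny; ++j) {
      int row = nx * j;
      for (int i = 0; i < nx; ++i) {
        int p = row + i;
        double v = Vold[p];
        double lap =
            (fx[p] * ((i < nx - 1 ? Vold[p + 1] : v) - v) -
             (i > 0 ? fx[p - 1] * (v - Vold[p - 1]) : 0.0) +
             fy_[p] * ((j < ny - 1 ? Vold[p + nx] : v) - v) -
             (j > 0 ? fy_[p - nx] * (v - Vold[p - nx]) : 0.0)) * invdx2;
        double cpl = pt_cnt[p] ? couple_m[p] / P.cm : 0.0;
        double istim = (stim_on && stim_mask[p]) ? stim_amp : 0.0;
        if ((inactive_scar && scar[p]) || freeze_myo_ion) {
          ycol(MY_V)[p] = v + dt * (-istim + cpl + lap);
        } else {
          double *yp = ycol(MY_V);  // strided access via per-variable columns
          // assemble a per-point view: columns share index p
          double ytmp[N_MYO];
          for (int vv = 0; vv < N_MYO; ++vv) ytmp[vv] = Y[(size_t)vv * npts + p];
          ytmp[MY_V] = v;
          myo_step(ytmp, P, &tables, dt, istim, cpl, lap, rush_larsen);
          for (int vv = 0; vv < N_MYO; ++vv) Y[(size_t)vv * npts + p] = ytmp[vv];
          (void)yp;
        }
        double vn = ycol(MY_V)[p];
        if (!(vn > -200.0 && vn < 200.0))
          stop("tissue integration unstable at t = %.2f ms, point (%d, %d)",
               t, i + 1, j + 1);
      }
    }

    // fibroblast units (driven by pre-step myocyte voltages)
    for (int u = 0; u < nunits; ++u) {
      double vf = fcol(FB_V)[u], csum = 0.0;
      for (int l = unit_ptr[u]; l < unit_ptr[u + 1]; ++l)
        csum += gs * (Vold[unit_pts[l]] - vf);
      tot_f += FP.nf * csum;
      double yf[N_FIB] = {vf, fcol(FB_R)[u], fcol(FB_S)[u]};
      fib_step(yf, FP, dt, csum, rush_larsen, freeze_fib_ion);
      if (!(yf[FB_V] > -200.0 && yf[FB_V] < 200.0))
        stop("fibroblast unit %d unstable at t = %.2f ms", u + 1, t);
      fcol(FB_V)[u] = yf[FB_V]; fcol(FB_R)[u] = yf[FB_R];
      fcol(FB_S)[u] = yf[FB_S];
    }
    if (std::fabs(tot_m + tot_f) > balance_max)
      balance_max = std::fabs(tot_m + tot_f);

    double tnew = t0 + (s + 1) * dt;
    // activation detection (upward crossings with refractory lockout)
    for (int p = 0; p < npts; ++p) {
      double vn = ycol(MY_V)[p];
      if (Vold[p] < act_thresh && vn >= act_thresh &&
          tnew - last_act[p] >= act_lockout) {
        last_act[p] = tnew;
        if (n_act[p] < max_act) act(p, n_act[p]) = tnew;
        ++n_act[p];
        if (want_exit && is_exit[p]) { stopped = true; stop_time = tnew; }
      }
      Vold[p] = vn;
    }

    if (line_stride > 0 && (s + 1) % line_stride == 0 && klrec < nlrec)
      rec_line(klrec++, tnew);
    if (snap_stride > 0 && (s + 1) % snap_stride == 0 && ksnap < nsnap)
      rec_snap(ksnap++, tnew);
    if ((s & 0x3FF) == 0) checkUserInterrupt();
  }

  NumericMatrix fin_myo(npts, N_MYO);
  std::copy(Y.begin(), Y.end(), fin_myo.begin());
  NumericMatrix fin_fib(nunits, N_FIB);
  std::copy(Fy.begin(), Fy.end(), fin_fib.begin());

  return List::create(
      _["final_myo"] = fin_myo, _["final_fib"] = fin_fib,
      _["line_t"] = line_t, _["line_v"] = line_v,
      _["fib_v"] = record_fib ? (SEXP)fib_v : R_NilValue,
      _["snap_t"] = snap_t, _["snaps"] = snaps, _["n_snap"] = (int)nsnap,
      _["act"] = act, _["n_act"] = n_act,
      _["stop_time"] = stop_time, _["balance_max"] = balance_max,
      _["n_line_rec"] = (int)klrec, _["n_snap_rec"] = (int)ksnap,
      _["t_end"] = t0 + (double)nsteps * dt, _["stopped"] = stopped);
}
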