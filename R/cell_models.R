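# Cell models: TP06 ventricular myocyte (shallow-restitution set) and
# MacCannell active fibroblast, plus the Gs coupling primitive, resting-
# potential calibration and the S1S2 restitution driver.

.myo_state_names <- c("v", "m", "h", "j", "xr1", "xr2", "xs", "r", "s",
                      "d", "f", "f2", "fcass", "cai", "cass", "casr",
                      "nai", "ki", "rbar")
.fib_state_names <- c("vf", "r", "s")

# Kv gating-voltage shifts (mV) reproducing the two fibroblast resting-
# potential variants, calibrated once with calibrate_vfr_shift() at
# dt = 0.01 ms / 20 s settling and frozen here so tissue runs are
# deterministic. Re-derived (to 0.1 mV in resting Vf) by the test suite.
.kv_shift_depolarized <- 34.78066113488     # resting Vf = -24.5 mV
.kv_shift_hyperpolarized <- 0.1885093042557 # resting Vf = -49.0 mV

#' TP06 myocyte parameter set
#'
#' Maximal conductances and fixed constants of the ten Tusscher-Panfilov
#' (2006) epicardial human ventricular myocyte, using the shallow-restitution
#' variant: default epicardial conductances with the L-type calcium current
#' f-gate time constant halved, which flattens the dynamic restitution curve
#' to a maximum slope of about 0.7 (the default kinetics give about 1.1; see
#' \code{\link{dynamic_restitution}}).
#'
#' @param variant restitution variant; only \code{"shallow"} is provided.
#' @param ... named overrides of individual entries (e.g. \code{gkr = 0.16});
#'   intended for sensitivity checks, not study configurations.
#' @return a named list of class \code{"myocyte_params"}: the 12 current
#'   conductances/scales (nS/pF except \code{gcal}), \code{cm} (pF, 150),
#'   external ion concentrations (mM) and \code{tauf_scale}.
#' @export
myocyte_params <- function(variant = "shallow", ...) {
  variant <- match.arg(variant)
  p <- list(
    gna = 14.838, gk1 = 5.405, gto = 0.294, gkr = 0.153, gks = 0.392,
    gcal = 3.980e-5, gbna = 2.9e-4, gbca = 5.92e-4, gpca = 0.1238,
    gpk = 0.0146, p_nak = 2.724, k_naca = 1000,
    tauf_scale = 0.5, cm = 150, ko = 5.4, nao = 140, cao = 2,
    variant = variant)
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad)) stop("unknown myocyte parameter(s): ",
                          paste(bad, collapse = ", "))
    num <- setdiff(names(dots), "variant")
    if (any(vapply(dots[num], function(x) !is.numeric(x) || x < 0, TRUE)))
      stop("myocyte conductances and constants must be non-negative numbers")
    p[names(dots)] <- dots
  }
  if (p$cm <= 0) stop("cm must be positive")
  structure(p, class = "myocyte_params")
}

#' MacCannell fibroblast-unit parameter set
#'
#' One fibroblast unit lumps \code{nf} identical MacCannell active
#' fibroblasts in parallel; all share one membrane potential and each
#' carries its own gap junction of Gs to every attached myocyte grid point,
#' so the effective unit-to-point conductance is \code{nf * gs}. The
#' resting potential variant is set by shifting the voltage dependence of
#' the time-dependent potassium (Kv) gating.
#'
#' @param vfr resting-potential variant: \code{"depolarized"} (-24.5 mV),
#'   \code{"hyperpolarized"} (-49.0 mV) or \code{"native"} (unshifted
#'   MacCannell model, about -49.6 mV).
#' @param nf fibroblasts per unit; the study configurations use 4, 6 or 8.
#' @param cf capacitance per fibroblast (pF); 50 pF corresponds to the
#'   larger myofibroblast.
#' @param kv_shift optional explicit Kv gating shift (mV), overriding the
#'   calibrated variant value.
#' @return a named list of class \code{"fibroblast_params"}.
#' @export
fibroblast_params <- function(vfr = c("depolarized", "hyperpolarized",
                                      "native"),
                              nf = 8, cf = 50, kv_shift = NULL) {
  vfr <- match.arg(vfr)
  if (!is.numeric(nf) || length(nf) != 1 || nf < 1)
    stop("nf must be a positive count")
  if (cf <= 0) stop("cf must be positive")
  shift <- switch(vfr,
                  depolarized = .kv_shift_depolarized,
                  hyperpolarized = .kv_shift_hyperpolarized,
                  native = 0)
  if (!is.null(kv_shift)) shift <- kv_shift
  target <- switch(vfr, depolarized = -24.5, hyperpolarized = -49.0,
                   native = NA_real_)
  structure(list(
    cf = cf, nf = nf, gkv = 0.25, gk1 = 0.4822, gbna = 0.0095,
    inak_max = 2.002, kmk = 1, kmna = 11, vrev = -150,
    ki = 129.4349, nai = 8.5547, ko = 5.3581, nao = 130.0110,
    kv_shift = shift, vfr = vfr, vfr_target = target),
    class = "fibroblast_params")
}

#' Resting initial state of the TP06 myocyte
#'
#' The published TP06 resting initial conditions. For protocols the cell is
#' additionally equilibrated quiescently (see
#' \code{\link{equilibrate_myocyte}}).
#' @return named numeric vector of the 19 state variables (V in mV, gates
#'   dimensionless, concentrations mM).
#' @export
myocyte_initial_state <- function() {
  setNames(cpp_myocyte_initial(), .myo_state_names)
}

#' Initial state of a fibroblast unit
#'
#' @param params \code{\link{fibroblast_params}}.
#' @param vf initial membrane potential (mV); defaults to the variant's
#'   resting target (or -49.6 mV for the native variant). Gates start at
#'   their steady state for \code{vf}.
#' @return named numeric vector (vf, r, s).
#' @export
fibroblast_initial_state <- function(params = fibroblast_params(),
                                     vf = NULL) {
  if (is.null(vf))
    vf <- if (is.na(params$vfr_target)) -49.6 else params$vfr_target
  setNames(cpp_fibroblast_initial(unclass(params), vf), .fib_state_names)
}

#' Myocyte membrane currents
#'
#' Evaluates the 12 TP06 membrane currents and their sum at a given state.
#' @param state named myocyte state vector (see
#'   \code{\link{myocyte_initial_state}}).
#' @param params \code{\link{myocyte_params}}.
#' @return named list: the 12 currents and \code{i_ion}, all in pA/pF
#'   (outward positive).
#' @export
myocyte_currents <- function(state, params = myocyte_params()) {
  cpp_myocyte_currents(.as_myo_state(state), unclass(params))
}

#' Fibroblast membrane currents
#'
#' The four MacCannell active-fibroblast currents (per pF of fibroblast
#' membrane; unaffected by the nf lumping) with the configured Kv shift.
#' @param state named fibroblast state (vf, r, s).
#' @param params \code{\link{fibroblast_params}}.
#' @return named list: \code{i_kv}, \code{i_k1}, \code{i_nak}, \code{i_bna}
#'   and their sum \code{i_ion} (pA/pF).
#' @export
fibroblast_currents <- function(state, params = fibroblast_params()) {
  cpp_fibroblast_currents(.as_fib_state(state), unclass(params))
}

#' Gap-junctional coupling current
#'
#' Current through one M-F gap junction, positive into the myocyte:
#' \code{gs * (vf - v)} (pA). The current into the fibroblast side of the
#' same junction is its exact negative. A fibroblast unit of \code{nf}
#' parallel fibroblasts contributes \code{nf} such junctions per attached
#' grid point.
#' @param v myocyte potential (mV).
#' @param vf fibroblast potential (mV).
#' @param gs junctional conductance (nS), non-negative.
#' @return current in pA (vectorized).
#' @export
coupling_current <- function(v, vf, gs) {
  if (any(gs < 0)) stop("gs must be non-negative")
  gs * (vf - v)
}

.as_myo_state <- function(state) {
  if (!is.numeric(state) || length(state) != length(.myo_state_names))
    stop("myocyte state must be a numeric vector of length ",
         length(.myo_state_names))
  if (!is.null(names(state))) state <- state[.myo_state_names]
  setNames(as.numeric(state), .myo_state_names)
}

.as_fib_state <- function(state) {
  if (!is.numeric(state) || length(state) != length(.fib_state_names))
    stop("fibroblast state must be a numeric vector of length ",
         length(.fib_state_names))
  if (!is.null(names(state))) state <- state[.fib_state_names]
  setNames(as.numeric(state), .fib_state_names)
}

#' Integrate a single myocyte (optionally coupled to a fibroblast unit)
#'
#' Forward-Euler integration at \code{dt} (default 0.01 ms) of a 0D TP06
#' myocyte, optionally attached to one fibroblast unit through a junction of
#' \code{gs} nS per fibroblast.
#'
#' @param duration total time (ms).
#' @param stim_times stimulus onset times (ms).
#' @param stim_amp stimulus amplitude in pA/pF (negative depolarizes;
#'   default -52, about twice diastolic threshold).
#' @param stim_dur stimulus duration (ms).
#' @param init initial myocyte state.
#' @param params \code{\link{myocyte_params}}.
#' @param fib_params \code{\link{fibroblast_params}}; used when
#'   \code{fib_init} is supplied.
#' @param fib_init initial fibroblast state, or \code{NULL} for an
#'   uncoupled myocyte.
#' @param gs junctional conductance (nS per fibroblast).
#' @param dt time step (ms).
#' @param record_dt trace sampling interval (ms).
#' @param record_states also record the full 19-variable state trajectory.
#' @param rush_larsen exponential (Rush-Larsen) gate updates (default): the
#'   fast INa activation gate makes plain forward-Euler gate updates
#'   unstable at any practical dt. Voltage and concentrations are always
#'   forward Euler.
#' @param use_tables evaluate the voltage-dependent rate functions from
#'   the solver's lookup tables instead of directly (the 2D solver always
#'   uses tables; this switch exists to quantify the table error).
#' @return list with \code{trace} (data.frame time/v/vf), optional
#'   \code{states} matrix, and \code{final_myo}/\code{final_fib} states.
#' @export
run_myocyte <- function(duration, stim_times = numeric(), stim_amp = -52,
                        stim_dur = 1, init = myocyte_initial_state(),
                        params = myocyte_params(),
                        fib_params = fibroblast_params(), fib_init = NULL,
                        gs = 0, dt = 0.01, record_dt = 1,
                        record_states = FALSE, rush_larsen = TRUE,
                        use_tables = FALSE) {
  out <- cpp_run_cell(.as_myo_state(init), unclass(params),
                      if (is.null(fib_init)) NULL else .as_fib_state(fib_init),
                      unclass(fib_params), gs, duration, dt,
                      as.numeric(stim_times), stim_dur, stim_amp,
                      record_dt, record_states, rush_larsen, use_tables)
  trace <- data.frame(time = out$time, v = out$v, vf = out$vf)
  states <- out$states
  if (!is.null(states)) colnames(states) <- .myo_state_names
  list(trace = trace, states = states,
       final_myo = setNames(out$final_myo, .myo_state_names),
       final_fib = if (is.null(out$final_fib)) NULL else
         setNames(out$final_fib, .fib_state_names))
}

#' Integrate an uncoupled fibroblast unit
#'
#' @param duration total time (ms).
#' @param init initial state (default: variant resting target).
#' @param params \code{\link{fibroblast_params}}.
#' @param dt time step (ms).
#' @param record_dt sampling interval (ms).
#' @return list with \code{trace} (time, vf, r, s) and \code{final_fib}.
#' @export
run_fibroblast <- function(duration, init = NULL,
                           params = fibroblast_params(), dt = 0.01,
                           record_dt = 10) {
  if (is.null(init)) init <- fibroblast_initial_state(params)
  out <- cpp_run_fibroblast(.as_fib_state(init), unclass(params),
                            duration, dt, record_dt)
  list(trace = data.frame(time = out$time, vf = out$vf, r = out$r,
                          s = out$s),
       final_fib = setNames(out$final_fib, .fib_state_names))
}

#' Quiescently equilibrated myocyte resting state
#'
#' Integrates the TP06 cell without stimulus for \code{duration} ms from the
#' published initial conditions; used as the tissue resting state. Cached
#' per parameter set within a session.
#' @param params \code{\link{myocyte_params}}.
#' @param duration equilibration time (ms, default 2000).
#' @param dt time step (ms).
#' @return named myocyte state vector.
#' @export
equilibrate_myocyte <- function(params = myocyte_params(),
                                duration = 2000, dt = 0.01) {
  key <- paste0("rest_", paste(unlist(params), collapse = "_"),
                "_", duration, "_", dt)
  if (!is.null(.flk_cache[[key]])) return(.flk_cache[[key]])
  st <- run_myocyte(duration, params = params, dt = dt,
                    record_dt = duration)$final_myo
  .flk_cache[[key]] <- st
  st
}

#' Steady resting potential of an uncoupled fibroblast unit
#'
#' @param params \code{\link{fibroblast_params}}.
#' @param settle_ms quiescent integration time (ms); the slow Kv
#'   inactivation gate needs ~20 s.
#' @param dt time step (ms).
#' @param v0 starting potential (mV).
#' @return terminal membrane potential (mV).
#' @export
fibroblast_resting_potential <- function(params = fibroblast_params(),
                                         settle_ms = 20000, dt = 0.01,
                                         v0 = -50) {
  init <- fibroblast_initial_state(params, vf = v0)
  run_fibroblast(settle_ms, init = init, params = params, dt = dt,
                 record_dt = settle_ms)$final_fib[["vf"]]
}

#' Calibrate the Kv gating shift for a target fibroblast resting potential
#'
#' Finds, by bracketed root search, the voltage shift of the Kv gating
#' functions for which the uncoupled fibroblast unit settles to the target
#' resting potential. Steady-state Vf is monotone increasing in the shift.
#'
#' @param target_vfr target resting potential (mV), in [-60, -10].
#' @param params base \code{\link{fibroblast_params}} (its own
#'   \code{kv_shift} is ignored).
#' @param bracket search interval for the shift (mV). Over the default
#'   non-negative bracket the steady resting potential is monotone
#'   increasing in the shift (a positive shift moves Kv activation away
#'   from the resting potential; large negative shifts instead remove Kv
#'   through its inactivation gate, so the map is not monotone there).
#' @param settle_ms quiescent settling time per evaluation (ms).
#' @param dt time step (ms).
#' @param tol_mv calibration tolerance on the resting potential (mV).
#' @return the shift (mV); the re-simulated resting potential is within
#'   \code{tol_mv} of the target.
#' @export
calibrate_vfr_shift <- function(target_vfr, params = fibroblast_params("native"),
                                bracket = c(0, 60), settle_ms = 20000,
                                dt = 0.01, tol_mv = 0.1) {
  if (target_vfr < -60 || target_vfr > -10)
    stop("target_vfr must lie in [-60, -10] mV")
  steady <- function(shift) {
    p <- params
    p$kv_shift <- shift
    fibroblast_resting_potential(p, settle_ms = settle_ms, dt = dt,
                                 v0 = target_vfr)
  }
  lo <- steady(bracket[1]); hi <- steady(bracket[2])
  if (abs(lo - target_vfr) <= tol_mv) return(bracket[1])
  if (abs(hi - target_vfr) <= tol_mv) return(bracket[2])
  if ((lo - target_vfr) * (hi - target_vfr) > 0)
    stop(sprintf(paste0("target %.1f mV unreachable: achievable resting ",
                        "range for shifts in [%g, %g] is [%.2f, %.2f] mV"),
                 target_vfr, bracket[1], bracket[2], lo, hi))
  root <- uniroot(function(s) steady(s) - target_vfr,
                  interval = bracket, tol = 1e-4)
  vrest <- steady(root$root)
  if (abs(vrest - target_vfr) > tol_mv)
    stop(sprintf("calibration failed: achieved %.3f mV for target %.1f mV",
                 vrest, target_vfr))
  root$root
}

#' S1S2 action potential duration restitution
#'
#' Applies a train of \code{n_s1} S1 stimuli at \code{s1_period}, then one
#' premature S2 at each coupling interval, and measures APD90 of the S2
#' beat against the preceding diastolic interval. The maximum restitution
#' slope is the largest finite difference between adjacent captured points
#' of the APD(DI) curve.
#'
#' @param params \code{\link{myocyte_params}}.
#' @param s1_period S1 cycle length (ms).
#' @param n_s1 number of S1 beats (>= 10 recommended to reach a periodic
#'   steady state).
#' @param s2_intervals S2 coupling intervals (ms after the last S1).
#' @param gs per-fibroblast junctional conductance (nS); 0 for the plain
#'   single myocyte.
#' @param fib_params fibroblast unit attached when \code{gs > 0}.
#' @param dt time step (ms).
#' @param stim_amp,stim_dur stimulus (pA/pF, ms).
#' @param equilibrate_ms quiescent equilibration before the S1 train (ms).
#' @return list with \code{curve} (data.frame: s2_interval, di, apd,
#'   captured), \code{s1_apd} (steady APD of the last S1 beat, ms) and
#'   \code{max_slope}.
#' @export
s1s2_restitution <- function(params = myocyte_params(), s1_period = 1000,
                             n_s1 = 10,
                             s2_intervals = c(seq(1000, 600, -100),
                                              seq(550, 400, -25),
                                              seq(390, 300, -10),
                                              seq(296, 240, -4)),
                             gs = 0, fib_params = fibroblast_params(),
                             dt = 0.01, stim_amp = -52, stim_dur = 1,
                             equilibrate_ms = 2000) {
  if (n_s1 < 2) stop("n_s1 must be at least 2")
  with_fib <- gs > 0
  fib0 <- if (with_fib) fibroblast_initial_state(fib_params) else NULL
  # equilibrate, then all S1 beats except the last
  pre <- run_myocyte(equilibrate_ms + (n_s1 - 1) * s1_period,
                     stim_times = equilibrate_ms + (0:(n_s1 - 2)) * s1_period,
                     stim_amp = stim_amp, stim_dur = stim_dur,
                     params = params, fib_params = fib_params,
                     fib_init = fib0, gs = gs, dt = dt,
                     record_dt = s1_period)
  base_myo <- pre$final_myo
  base_fib <- pre$final_fib

  one <- function(s2) {
    run_myocyte(s2 + 800, stim_times = c(0, s2), stim_amp = stim_amp,
                stim_dur = stim_dur, init = base_myo, params = params,
                fib_params = fib_params, fib_init = base_fib, gs = gs,
                dt = dt, record_dt = 0.25)
  }
  rows <- lapply(s2_intervals, function(s2) {
    tr <- one(s2)$trace
    acts <- detect_activations(tr$time, tr$v)
    apds <- compute_apd(tr$time, tr$v, activations = acts)
    s1_apd <- if (nrow(apds) >= 1) apds$apd[1] else NA_real_
    # capture = a true S2 action potential: activation near the S2 time,
    # full upstroke (not a graded response riding the repolarization tail)
    # and complete repolarization inside the window
    captured <- nrow(apds) >= 2 && abs(apds$t_act[2] - s2) < stim_dur + 20 &&
      apds$v_peak[2] > 0 && (apds$v_peak[2] - apds$v_rest[2]) > 60 &&
      apds$repolarized[2]
    data.frame(s2_interval = s2,
               di = if (is.na(s1_apd)) NA_real_ else s2 - s1_apd,
               apd = if (captured) apds$apd[2] else NA_real_,
               s1_apd = s1_apd, captured = captured)
  })
  curve <- do.call(rbind, rows)
  curve <- curve[order(curve$di), ]
  rownames(curve) <- NULL
  cap <- curve[curve$captured & !is.na(curve$apd), ]
  max_slope <- if (nrow(cap) >= 2) {
    max(diff(cap$apd) / diff(cap$di))
  } else NA_real_
  s1_ref <- if (nrow(cap)) cap$s1_apd else curve$s1_apd
  list(curve = curve, s1_apd = median(s1_ref, na.rm = TRUE),
       max_slope = max_slope)
}

#' Dynamic (steady-state pacing) APD restitution
#'
#' Paces the cell to a periodic steady state at each cycle length and
#' records the steady APD90 against the steady diastolic interval; the
#' maximum slope is taken between adjacent cycle lengths. This is the
#' protocol under which the restitution variants are defined: the shallow
#' set has a maximum dynamic slope of about 0.7 versus about 1.1 for the
#' default kinetics. Pacing stops at the first cycle length that loses 1:1
#' capture or develops APD alternans.
#'
#' @param params \code{\link{myocyte_params}}.
#' @param cycle_lengths pacing cycle lengths (ms), decreasing.
#' @param n_beats beats per cycle length (the last three must agree within
#'   the alternans tolerance to count as steady).
#' @param alternans_tol APD spread (ms) above which pacing is considered
#'   non-steady and the scan stops.
#' @param gs,fib_params optional fibroblast unit as in
#'   \code{\link{s1s2_restitution}}.
#' @param dt time step (ms).
#' @param equilibrate_ms quiescent equilibration before pacing (ms).
#' @return list with \code{curve} (data.frame: cl, apd, di) and
#'   \code{max_slope}.
#' @export
dynamic_restitution <- function(params = myocyte_params(),
                                cycle_lengths = c(1000, 800, 650, 550, 470,
                                                  420, 380, 350, 330, 315,
                                                  300, 290, 280, 270, 260,
                                                  250, 240, 230),
                                n_beats = 25, alternans_tol = 5, gs = 0,
                                fib_params = fibroblast_params(), dt = 0.01,
                                equilibrate_ms = 2000) {
  with_fib <- gs > 0
  fib0 <- if (with_fib) fibroblast_initial_state(fib_params) else NULL
  pre <- run_myocyte(equilibrate_ms, params = params,
                     fib_params = fib_params, fib_init = fib0, gs = gs,
                     dt = dt, record_dt = equilibrate_ms)
  st <- pre$final_myo
  stf <- pre$final_fib
  rows <- NULL
  for (cl in sort(cycle_lengths, decreasing = TRUE)) {
    r <- run_myocyte(n_beats * cl, stim_times = (0:(n_beats - 1)) * cl,
                     init = st, params = params, fib_params = fib_params,
                     fib_init = stf, gs = gs, dt = dt, record_dt = 0.5)
    st <- r$final_myo
    stf <- r$final_fib
    ap <- compute_apd(r$trace$time, r$trace$v)
    ap <- ap[ap$repolarized & !is.na(ap$cl), ]
    if (nrow(ap) < n_beats - 2) break  # loss of 1:1 capture
    last <- tail(ap, 3)
    if (diff(range(last$apd)) > alternans_tol) break
    rows <- rbind(rows, data.frame(cl = cl, apd = mean(last$apd),
                                   di = mean(last$di)))
  }
  if (is.null(rows))
    stop("no cycle length sustained steady 1:1 capture")
  max_slope <- if (nrow(rows) >= 2)
    max(diff(rows$apd) / diff(rows$di)) else NA_real_
  list(curve = rows, max_slope = max_slope)
}
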