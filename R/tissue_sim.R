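# 2D monodomain simulation: configuration, the diffusion operator, and the
# forward-Euler tissue runner (C++ core).

#' Simulation configuration
#'
#' Bundles geometry, link set and numerical settings for a tissue run and
#' validates the explicit-scheme stability bound \code{4 D dt / dx^2 < 1}.
#'
#' @param geom \code{\link{tissue_geometry}}.
#' @param links \code{\link{link_set}} or NULL.
#' @param gs junctional conductance per fibroblast per link (nS).
#' @param nf fibroblasts per unit.
#' @param dt time step (ms; default 0.01).
#' @param duration default run duration (ms).
#' @param scar_mode \code{"active"} (scar myocytes keep their ionic
#'   currents) or \code{"inactive"} (I_ion = 0 in the scar; scar V still
#'   evolves through the M-F coupling).
#' @param vfr fibroblast resting-potential variant (see
#'   \code{\link{fibroblast_params}}).
#' @param snapshot_dt field snapshot cadence (ms; 0 disables).
#' @param line_dt sampling-line trace cadence (ms; 0 disables).
#' @param equilibrate_ms quiescent pre-protocol equilibration of the
#'   coupled tissue (ms). The 0D resting states are already equilibrated;
#'   this settles the link neighbourhoods.
#' @param stim_amp,stim_dur default stimulus (pA/pF, ms).
#' @param act_threshold,act_lockout activation-detection threshold (mV) and
#'   refractory lockout (ms) for the activation log.
#' @param max_act maximum activations logged per grid point.
#' @param rush_larsen exponential (Rush-Larsen) gate updates (default;
#'   required for stability of the fast INa gate). Voltage and
#'   concentrations are always forward Euler.
#' @param seed seed recorded for provenance (the solver itself is
#'   deterministic).
#' @return object of class \code{"sim_config"}.
#' @export
sim_config <- function(geom, links = NULL, gs = 1, nf = 8, dt = 0.01,
                       duration = 1000,
                       scar_mode = c("active", "inactive"),
                       vfr = "depolarized", snapshot_dt = 20, line_dt = 1,
                       equilibrate_ms = 250, stim_amp = -52, stim_dur = 1,
                       act_threshold = -40, act_lockout = 50,
                       max_act = 40, rush_larsen = TRUE, seed = NA) {
  scar_mode <- match.arg(scar_mode)
  stopifnot(inherits(geom, "tissue_geometry"))
  if (gs < 0) stop("gs must be non-negative")
  if (dt <= 0) stop("dt must be positive")
  d_mm2 <- geom$d_reg * 100  # cm^2/ms -> mm^2/ms
  if (4 * d_mm2 * dt / geom$dx^2 >= 1)
    stop(sprintf("explicit scheme unstable: 4 D dt / dx^2 = %.3f >= 1",
                 4 * d_mm2 * dt / geom$dx^2))
  if (!is.null(links) && (links$nx != geom$nx || links$ny != geom$ny))
    stop("link set was generated for a different lattice")
  structure(list(geom = geom, links = links, gs = gs, nf = nf, dt = dt,
                 duration = duration, scar_mode = scar_mode, vfr = vfr,
                 snapshot_dt = snapshot_dt, line_dt = line_dt,
                 equilibrate_ms = equilibrate_ms, stim_amp = stim_amp,
                 stim_dur = stim_dur, act_threshold = act_threshold,
                 act_lockout = act_lockout, max_act = max_act,
                 rush_larsen = rush_larsen, seed = seed),
            class = "sim_config")
}

#' Discrete diffusion operator
#'
#' Flux-conservative five-point discretization of div(D grad V) with face
#' diffusivity zero whenever either adjacent point is scar, and mirrored
#' ghost points (no flux) at the domain edges. This is the reference R
#' implementation of the operator used inside the C++ solver.
#'
#' @param v nx x ny voltage field (mV).
#' @param geom \code{\link{tissue_geometry}}.
#' @return nx x ny matrix of dV/dt contributions (mV/ms).
#' @export
diffusion_term <- function(v, geom) {
  nx <- geom$nx; ny <- geom$ny
  stopifnot(is.matrix(v), nrow(v) == nx, ncol(v) == ny)
  d_mm2 <- geom$d_reg * 100
  s <- geom$scar
  fx <- matrix(0, nx, ny)  # face between (i, j) and (i+1, j)
  fx[-nx, ] <- ifelse(!s[-nx, ] & !s[-1, ], d_mm2, 0)
  fy <- matrix(0, nx, ny)  # face between (i, j) and (i, j+1)
  fy[, -ny] <- ifelse(!s[, -ny] & !s[, -1], d_mm2, 0)
  flux_e <- matrix(0, nx, ny)
  flux_e[-nx, ] <- fx[-nx, ] * (v[-1, ] - v[-nx, ])
  flux_n <- matrix(0, nx, ny)
  flux_n[, -ny] <- fy[, -ny] * (v[, -1] - v[, -ny])
  lap <- flux_e + flux_n
  lap[-1, ] <- lap[-1, ] - flux_e[-nx, ]
  lap[, -1] <- lap[, -1] - flux_n[, -ny]
  lap / geom$dx^2
}

# broadcast resting states for a fresh tissue state
.tissue_initial <- function(cfg, myo_params, fib_params) {
  npts <- cfg$geom$nx * cfg$geom$ny
  rest <- equilibrate_myocyte(myo_params)
  myo <- matrix(rest, npts, length(rest), byrow = TRUE)
  nunits <- if (is.null(cfg$links)) 0L else cfg$links$n_units
  fib <- if (nunits > 0) {
    f0 <- fibroblast_initial_state(fib_params)
    matrix(f0, nunits, length(f0), byrow = TRUE)
  } else matrix(0, 0, 3)
  list(myo = myo, fib = fib)
}

#' Run a 2D tissue simulation
#'
#' Forward-Euler integration of the myocyte field (ionic + diffusion +
#' M-F coupling + stimulus) and the fibroblast units. Both sides of every
#' link are evaluated at the same pre-step voltages, so the coupling charge
#' is antisymmetric at every step. The run is deterministic for a given
#' configuration.
#'
#' @param cfg \code{\link{sim_config}}.
#' @param protocol \code{\link{pacing_protocol}}.
#' @param duration override of \code{cfg$duration} (ms).
#' @param init optional initial state (list \code{myo}, \code{fib}) as
#'   returned in \code{$final} of a previous recording; skips
#'   equilibration.
#' @param myo_params,fib_params cell parameter overrides.
#' @param exit_on activation of any of these grid points stops the run
#'   early (matrix of i, j or vector of point indices); used by conduction
#'   tests.
#' @param record_fib record fibroblast-unit voltages at the line cadence.
#' @return object of class \code{"tissue_recording"}: line traces
#'   (\code{line_t}, \code{line_v}), snapshots (\code{snap_t},
#'   \code{snaps} array nx x ny x n), activation log (\code{act} matrix,
#'   \code{n_act}), final states, coupling-balance diagnostic and the
#'   configuration.
#' @export
run_tissue <- function(cfg, protocol = pacing_protocol("none"),
                       duration = NULL, init = NULL,
                       myo_params = myocyte_params(),
                       fib_params = NULL, exit_on = NULL,
                       record_fib = FALSE) {
  stopifnot(inherits(cfg, "sim_config"))
  geom <- cfg$geom
  nx <- geom$nx; ny <- geom$ny; npts <- nx * ny
  if (is.null(fib_params))
    fib_params <- fibroblast_params(cfg$vfr, nf = cfg$nf)
  if (is.null(duration)) duration <- cfg$duration
  csr <- .links_csr(cfg$links)

  if (is.null(init)) {
    init <- .tissue_initial(cfg, myo_params, fib_params)
    if (cfg$equilibrate_ms > 0 && csr$n_units > 0) {
      eq <- cpp_run_tissue(nx, ny, as.integer(geom$scar), geom$d_reg * 100,
                           geom$dx, unclass(myo_params),
                           unclass(fib_params), init$myo, init$fib,
                           csr$unit_ptr, csr$unit_pts, cfg$gs,
                           cfg$scar_mode == "inactive",
                           -cfg$equilibrate_ms, cfg$dt,
                           round(cfg$equilibrate_ms / cfg$dt),
                           numeric(), 0, 0, integer(), integer(), 0L, 0L,
                           cfg$act_threshold, cfg$act_lockout, 1L,
                           integer(), FALSE, FALSE, FALSE,
                           cfg$rush_larsen)
      init <- list(myo = eq$final_myo, fib = eq$final_fib)
    }
  }

  stim <- .protocol_stimulus(protocol, geom)
  line_idx <- .pt_index(geom$sampling_line[, 1], geom$sampling_line[, 2], nx)
  line_stride <- if (cfg$line_dt > 0) max(1L, round(cfg$line_dt / cfg$dt)) else 0L
  snap_stride <- if (cfg$snapshot_dt > 0)
    max(1L, round(cfg$snapshot_dt / cfg$dt)) else 0L
  exit_idx <- if (is.null(exit_on)) integer() else {
    if (is.matrix(exit_on)) .pt_index(exit_on[, 1], exit_on[, 2], nx) - 1L
    else as.integer(exit_on) - 1L
  }

  nsteps <- round(duration / cfg$dt)
  out <- cpp_run_tissue(nx, ny, as.integer(geom$scar), geom$d_reg * 100,
                        geom$dx, unclass(myo_params), unclass(fib_params),
                        init$myo, init$fib, csr$unit_ptr, csr$unit_pts,
                        cfg$gs, cfg$scar_mode == "inactive", 0, cfg$dt,
                        nsteps, stim$times, stim$dur, stim$amp,
                        stim$idx - 1L, line_idx - 1L, line_stride,
                        snap_stride, cfg$act_threshold, cfg$act_lockout,
                        cfg$max_act, exit_idx, record_fib, FALSE, FALSE,
                        cfg$rush_larsen)

  nl <- out$n_line_rec
  nsn <- min(out$n_snap_rec, out$n_snap)
  snaps <- if (out$n_snap > 0 && nsn > 0)
    array(out$snaps[seq_len(as.numeric(nsn) * npts)], dim = c(nx, ny, nsn))
  else NULL
  structure(list(
    line_t = if (line_stride > 0) out$line_t[seq_len(nl)] else numeric(),
    line_v = if (line_stride > 0)
      out$line_v[seq_len(nl), , drop = FALSE] else NULL,
    line_idx = line_idx,
    fib_v = if (record_fib && line_stride > 0)
      out$fib_v[seq_len(min(nl, nrow(out$fib_v))), , drop = FALSE] else NULL,
    snap_t = if (!is.null(snaps)) out$snap_t[seq_len(nsn)] else numeric(),
    snaps = snaps,
    act = out$act, n_act = out$n_act,
    final = list(myo = out$final_myo, fib = out$final_fib),
    stop_time = out$stop_time, stopped = out$stopped,
    balance_max = out$balance_max, t_end = out$t_end,
    cfg = cfg, protocol = protocol),
    class = "tissue_recording")
}

#' @export
print.tissue_recording <- function(x, ...) {
  cat(sprintf(paste0("tissue_recording: %d x %d, t_end = %g ms, ",
                     "%d snapshots, %d activated points\n"),
              x$cfg$geom$nx, x$cfg$geom$ny, x$t_end,
              if (is.null(x$snaps)) 0L else dim(x$snaps)[3],
              sum(x$n_act > 0)))
  invisible(x)
}

#' Advance a tissue state by a number of steps
#'
#' Thin stepping interface over the same C++ core as
#' \code{\link{run_tissue}}: no equilibration, no recording, returns the
#' advanced state.
#' @param cfg \code{\link{sim_config}}.
#' @param state list(myo, fib) state matrices.
#' @param n_steps number of forward-Euler steps.
#' @param protocol optional stimulus protocol active during the steps.
#' @param t0 simulation time of the first step (ms; stimulus timing is
#'   absolute).
#' @param myo_params,fib_params cell parameter overrides.
#' @return advanced list(myo, fib).
#' @export
step_tissue <- function(cfg, state, n_steps = 1,
                        protocol = pacing_protocol("none"), t0 = 0,
                        myo_params = myocyte_params(), fib_params = NULL) {
  geom <- cfg$geom
  if (is.null(fib_params))
    fib_params <- fibroblast_params(cfg$vfr, nf = cfg$nf)
  csr <- .links_csr(cfg$links)
  stim <- .protocol_stimulus(protocol, geom)
  out <- cpp_run_tissue(geom$nx, geom$ny, as.integer(geom$scar),
                        geom$d_reg * 100, geom$dx, unclass(myo_params),
                        unclass(fib_params), state$myo, state$fib,
                        csr$unit_ptr, csr$unit_pts, cfg$gs,
                        cfg$scar_mode == "inactive", t0, cfg$dt, n_steps,
                        stim$times, stim$dur, stim$amp, stim$idx - 1L,
                        integer(), 0L, 0L, cfg$act_threshold,
                        cfg$act_lockout, 1L, integer(), FALSE, FALSE,
                        FALSE, cfg$rush_larsen)
  list(myo = out$final_myo, fib = out$final_fib,
       balance_max = out$balance_max)
}
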