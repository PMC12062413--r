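# Pacing protocols and the study's experiments: line-scar conduction test,
# circular-scar rapid pacing, and the lambda x np x Gs x realisation sweep.

#' Pacing protocol
#'
#' @param mode \code{"edge"} (plane waves from the x = 1 edge, stimulating
#'   a strip \code{depth} points deep), \code{"point"} (a 5x5 block at
#'   \code{site}), \code{"s1s2"} (edge S1 train plus one premature S2) or
#'   \code{"none"}.
#' @param period pacing period T (ms; the rapid-pacing protocol uses 300).
#' @param n_beats number of stimuli (20 beats at T = 300 ms spans 6 s).
#' @param stim_amp stimulus amplitude (pA/pF, negative depolarizes).
#' @param stim_dur stimulus duration (ms).
#' @param depth stimulated strip depth for edge pacing (grid points).
#' @param site centre (i, j) of the 5x5 point-pacing block.
#' @param s2_interval S2 coupling interval after the last S1 (ms), for
#'   \code{mode = "s1s2"}.
#' @return object of class \code{"pacing_protocol"}.
#' @export
pacing_protocol <- function(mode = c("edge", "point", "s1s2", "none"),
                            period = 300, n_beats = 20, stim_amp = -52,
                            stim_dur = 1, depth = 3, site = NULL,
                            s2_interval = NULL) {
  mode <- match.arg(mode)
  if (period <= 0) stop("period must be positive")
  if (n_beats < 1) stop("n_beats must be at least 1")
  if (mode == "s1s2" && is.null(s2_interval))
    stop("s1s2 mode needs s2_interval")
  structure(list(mode = mode, period = period, n_beats = n_beats,
                 stim_amp = stim_amp, stim_dur = stim_dur, depth = depth,
                 site = site, s2_interval = s2_interval),
            class = "pacing_protocol")
}

# stimulus times + stimulated point set for a protocol on a geometry
.protocol_stimulus <- function(protocol, geom) {
  nx <- geom$nx; ny <- geom$ny
  if (protocol$mode == "none")
    return(list(times = numeric(), dur = 0, amp = 0, idx = integer()))
  times <- (seq_len(protocol$n_beats) - 1) * protocol$period
  if (protocol$mode == "s1s2")
    times <- c(times, times[length(times)] + protocol$s2_interval)
  idx <- if (protocol$mode == "point") {
    site <- if (is.null(protocol$site)) c(3L, round(ny / 2)) else protocol$site
    ii <- pmax(1L, pmin(nx, site[1] + (-2:2)))
    jj <- pmax(1L, pmin(ny, site[2] + (-2:2)))
    as.vector(outer(ii, (jj - 1L) * nx, "+"))
  } else {
    as.vector(outer(seq_len(min(protocol$depth, nx)),
                    (seq_len(ny) - 1L) * nx, "+"))
  }
  list(times = times, dur = protocol$stim_dur, amp = protocol$stim_amp,
       idx = unique(idx))
}

#' Deterministic bridging links across a line scar
#'
#' The reference conduction-test wiring: one fibroblast unit per row,
#' proximal at the central scar column, attached to every scar cell of the
#' band in its row and to the nearest non-scar cell on each flank. The
#' unit thus relays the wave symmetrically across the scar purely through
#' M-F links, while the in-scar attachments load the unit so that the
#' relay engages only above a threshold effective conductance nf * gs
#' (one unit per row keeps the electrotonic load on each flank cell to a
#' single unit, so the approaching wave is not suppressed wholesale).
#' @param geom a line-scar \code{\link{tissue_geometry}}.
#' @param gs junctional conductance recorded on the links (nS).
#' @return a \code{\link{link_set}}.
#' @export
make_line_scar_links <- function(geom, gs = 4) {
  if (geom$scar_shape != "line") stop("needs a line-scar geometry")
  cols <- geom$scar_cols
  left <- min(cols) - 1L; right <- max(cols) + 1L
  centre <- cols[ceiling(length(cols) / 2)]
  prox <- integer(); dist <- list()
  for (j in seq_len(geom$ny)) {
    prox <- c(prox, .pt_index(centre, j, geom$nx))
    dist[[length(dist) + 1L]] <- c(.pt_index(setdiff(cols, centre), j,
                                             geom$nx),
                                   .pt_index(left, j, geom$nx),
                                   .pt_index(right, j, geom$nx))
  }
  l_need <- geom$dx * (max(cols) - left + 1)
  structure(list(proximal = prox, distal = dist, n_units = length(prox),
                 lambda = 0, l_max = max(2.5, l_need), seed = NA_integer_,
                 gs = gs, pool = "deterministic",
                 realisation = NA_integer_, nx = geom$nx, ny = geom$ny,
                 dx = geom$dx),
            class = "link_set")
}

#' Line-scar conduction test
#'
#' A single plane wave is paced from the x = 1 edge of a strip with a
#' vertical line scar bridged by deterministic M-F links
#' (\code{\link{make_line_scar_links}}). The wave can only reach the distal
#' side through the fibroblasts. Reports whether the distal tissue
#' activates and the activation-time delay across the scar, measured
#' between the rows of points immediately flanking the band on the
#' sampling row.
#'
#' @param gs junctional conductance (nS).
#' @param nf fibroblasts per unit.
#' @param geom line-scar geometry (default 200 x 60 strip, 5-column band).
#' @param duration maximum simulated time (ms); the run stops as soon as
#'   the distal flank activates.
#' @param vfr fibroblast resting-potential variant.
#' @param scar_mode active or inactive scar myocytes.
#' @param ... further \code{\link{sim_config}} settings.
#' @return list: \code{conducted}, \code{delay} (ms, NA if blocked),
#'   \code{recording}.
#' @export
line_scar_conduction_test <- function(gs, nf = 8, geom = NULL,
                                      duration = 600, vfr = "depolarized",
                                      scar_mode = "active", ...) {
  if (is.null(geom))
    geom <- tissue_geometry(200, 60, scar_shape = "line")
  links <- make_line_scar_links(geom, gs = gs)
  cfg <- sim_config(geom, links, gs = gs, nf = nf, duration = duration,
                    vfr = vfr, scar_mode = scar_mode, snapshot_dt = 0,
                    line_dt = 1, ...)
  protocol <- pacing_protocol("edge", period = duration, n_beats = 1)
  right <- max(geom$scar_cols) + 1L
  left <- min(geom$scar_cols) - 1L
  exit_pts <- cbind(i = right + 1L, j = seq_len(geom$ny))
  rec <- run_tissue(cfg, protocol, exit_on = exit_pts)
  j0 <- round((geom$ny + 1) / 2)
  t_left <- rec$act[.pt_index(left - 1L, j0, geom$nx), 1]
  t_right <- rec$act[.pt_index(right + 1L, j0, geom$nx), 1]
  conducted <- rec$stopped || any(rec$n_act[.pt_index(
    rep(right + 1L, geom$ny), seq_len(geom$ny), geom$nx)] > 0)
  delay <- if (conducted && !is.na(t_left) && !is.na(t_right))
    t_right - t_left else NA_real_
  list(conducted = conducted, delay = delay, recording = rec)
}

#' Rapid pacing of a scarred tissue with regime classification
#'
#' Runs the pacing protocol on the configured geometry/link set, then
#' classifies the outcome as NR, BR or PR from the activation log.
#' @param cfg \code{\link{sim_config}} (circular-scar geometry + links).
#' @param protocol \code{\link{pacing_protocol}} (default: 20 beats of
#'   edge pacing at T = 300 ms).
#' @param horizon_after_last extra simulated time after the last stimulus
#'   (ms; default two pacing periods, the die-out horizon).
#' @param ... passed to \code{\link{run_tissue}}.
#' @return list: \code{regime} (\code{\link{classify_regime}} result),
#'   \code{recording}.
#' @export
paced_scar_run <- function(cfg, protocol = pacing_protocol("edge"),
                           horizon_after_last = 2 * protocol$period, ...) {
  duration <- (protocol$n_beats - 1) * protocol$period +
    protocol$period + horizon_after_last
  rec <- run_tissue(cfg, protocol, duration = duration, ...)
  regime <- classify_regime(rec, cfg$geom, protocol,
                            l_max = if (is.null(cfg$links)) 0 else
                              cfg$links$l_max)
  list(regime = regime, recording = rec)
}

#' Parameter-sweep specification
#'
#' The study sweep: link density lambda, unit count np, five fixed spatial
#' realisations and four coupling strengths (the full grid enumerates
#' 3 x 3 x 5 x 4 = 180 runs).
#' @param lambda Poisson link-density values.
#' @param n_units fibroblast-unit counts (np).
#' @param realisations realisation ids (fixed seeds via
#'   \code{\link{realisation_seed}}).
#' @param gs coupling strengths (nS).
#' @param scar_mode active or inactive scar.
#' @param vfr fibroblast resting-potential variant.
#' @param l_max link distance cutoff (mm).
#' @return object of class \code{"sweep_spec"}.
#' @export
sweep_spec <- function(lambda = c(40, 50, 60),
                       n_units = c(10000, 20000, 30000),
                       realisations = 1:5, gs = c(1, 2, 3, 4),
                       scar_mode = "active", vfr = "depolarized",
                       l_max = 2.5) {
  structure(list(lambda = lambda, n_units = n_units,
                 realisations = realisations, gs = gs,
                 scar_mode = scar_mode, vfr = vfr, l_max = l_max),
            class = "sweep_spec")
}

#' Enumerate the sweep grid
#' @param spec \code{\link{sweep_spec}}.
#' @return data.frame with one row per run (lambda, n_units, realisation,
#'   gs, seed), the Cartesian product of the axes.
#' @export
sweep_grid <- function(spec) {
  g <- expand.grid(gs = spec$gs, realisation = spec$realisations,
                   n_units = spec$n_units, lambda = spec$lambda,
                   KEEP.OUT.ATTRS = FALSE)
  g <- g[, c("lambda", "n_units", "realisation", "gs")]
  g$seed <- realisation_seed(g$realisation)
  rownames(g) <- NULL
  g
}

#' Run the parameter sweep
#'
#' Executes one paced run per grid row and tabulates the regime labels.
#' Resumable: rows already present in \code{out_csv} are skipped.
#' @param spec \code{\link{sweep_spec}}.
#' @param geom circular-scar geometry (the full-study geometry is the
#'   200 x 200 lattice with the 2 cm scar).
#' @param protocol pacing protocol.
#' @param out_csv optional CSV path for incremental results.
#' @param runner function(cfg, protocol) returning a list with a
#'   \code{regime} element; defaults to \code{\link{paced_scar_run}}.
#'   Injectable for reduced-scale studies.
#' @param verbose print per-row progress.
#' @return data.frame: the grid plus \code{label} and \code{error}
#'   columns.
#' @export
run_sweep <- function(spec, geom, protocol = pacing_protocol("edge"),
                      out_csv = NULL, runner = NULL, verbose = TRUE) {
  grid <- sweep_grid(spec)
  if (is.null(runner))
    runner <- function(cfg, protocol) paced_scar_run(cfg, protocol)
  done <- NULL
  if (!is.null(out_csv) && file.exists(out_csv)) {
    done <- read.csv(out_csv)
  }
  key <- function(d) paste(d$lambda, d$n_units, d$realisation, d$gs)
  rows <- vector("list", nrow(grid))
  for (r in seq_len(nrow(grid))) {
    g <- grid[r, ]
    if (!is.null(done) && key(g) %in% key(done)) {
      rows[[r]] <- done[key(done) == key(g), ][1, ]
      next
    }
    res <- tryCatch({
      links <- generate_links(geom, g$n_units, g$lambda,
                              l_max = spec$l_max, seed = g$seed, gs = g$gs)
      cfg <- sim_config(geom, links, gs = g$gs,
                        scar_mode = spec$scar_mode, vfr = spec$vfr)
      out <- runner(cfg, protocol)
      data.frame(g, label = out$regime$label, error = NA_character_)
    }, error = function(e) data.frame(g, label = NA_character_,
                                      error = conditionMessage(e)))
    rows[[r]] <- res
    if (!is.null(out_csv))
      write.csv(do.call(rbind, rows[seq_len(r)]), out_csv,
                row.names = FALSE)
    if (verbose)
      message(sprintf("[%d/%d] lambda=%g np=%g real=%d gs=%g -> %s",
                      r, nrow(grid), g$lambda, g$n_units, g$realisation,
                      g$gs, rows[[r]]$label))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Marginal regime fractions of a sweep result
#'
#' Fraction of NR/BR/PR outcomes as a function of one sweep axis, summing
#' over the others.
#' @param result data.frame from \code{\link{run_sweep}}.
#' @param axis one of \code{"lambda"}, \code{"n_units"}, \code{"gs"},
#'   \code{"realisation"}.
#' @return data.frame: axis value, label, fraction (fractions sum to 1
#'   within each axis value).
#' @export
regime_fractions <- function(result, axis = c("lambda", "n_units", "gs",
                                              "realisation")) {
  axis <- match.arg(axis)
  ok <- !is.na(result$label)
  tb <- table(result[[axis]][ok],
              factor(result$label[ok], levels = c("NR", "BR", "PR")))
  fr <- prop.table(tb, margin = 1)
  out <- as.data.frame(fr, stringsAsFactors = FALSE)
  names(out) <- c(axis, "label", "fraction")
  out[[axis]] <- as.numeric(as.character(out[[axis]]))
  out
}
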