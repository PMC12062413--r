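# Trace and activation-map analyses: activation detection, APD90 series,
# local restitution curves, APD dispersion, space-time sections, and the
# NR/BR/PR reentry-regime classifier.

#' Detect activation times in a voltage trace
#'
#' Times of upward threshold crossings with a refractory lockout;
#' crossing times are linearly interpolated between samples.
#' @param t sample times (ms, uniformly increasing).
#' @param v membrane potential (mV).
#' @param threshold upstroke threshold (mV; default -40).
#' @param lockout refractory lockout (ms; default 50).
#' @return numeric vector of activation times (possibly empty).
#' @export
detect_activations <- function(t, v, threshold = -40, lockout = 50) {
  stopifnot(length(t) == length(v))
  if (length(t) < 2) return(numeric())
  up <- which(v[-1] >= threshold & v[-length(v)] < threshold)
  if (length(up) == 0) return(numeric())
  tc <- t[up] + (threshold - v[up]) / (v[up + 1] - v[up]) *
    (t[up + 1] - t[up])
  keep <- numeric(0)
  last <- -Inf
  for (x in tc) {
    if (x - last >= lockout) {
      keep <- c(keep, x)
      last <- x
    }
  }
  keep
}

#' Action potential durations (APD90) of a trace
#'
#' For each detected activation, APD is the time from the upstroke
#' crossing until the potential repolarizes through
#' \code{v_rest + (1 - frac) * (v_peak - v_rest)}, with the resting level
#' and peak measured per beat. Beats that do not repolarize before the
#' next activation (or the end of the trace) are flagged, not dropped.
#'
#' @param t,v trace (ms, mV).
#' @param activations activation times; detected with the default
#'   threshold when NULL.
#' @param frac repolarization fraction (0.9 for APD90).
#' @param threshold,lockout passed to \code{\link{detect_activations}}.
#' @return data.frame: \code{n}, \code{t_act}, \code{apd} (ms),
#'   \code{v_peak}, \code{v_rest}, \code{repolarized}, \code{cl} (ms,
#'   interval to next activation; NA for the last beat) and \code{di}
#'   (\code{cl - apd}).
#' @export
compute_apd <- function(t, v, activations = NULL, frac = 0.9,
                        threshold = -40, lockout = 50) {
  if (is.null(activations))
    activations <- detect_activations(t, v, threshold, lockout)
  n <- length(activations)
  empty <- data.frame(n = integer(), t_act = numeric(), apd = numeric(),
                      v_peak = numeric(), v_rest = numeric(),
                      repolarized = logical(), cl = numeric(),
                      di = numeric())
  if (n == 0) return(empty)
  rows <- lapply(seq_len(n), function(k) {
    a <- activations[k]
    b <- if (k < n) activations[k + 1] else max(t)
    # per-beat resting level: diastolic minimum over the 20 ms before the
    # upstroke (avoids sampling inside the stimulus artefact)
    pre <- which(t < a & t >= a - 20)
    v_rest <- if (length(pre)) min(v[pre]) else v[1]
    win <- t >= a & t <= b
    v_peak <- max(v[win])
    level <- v_rest + (1 - frac) * (v_peak - v_rest)
    tw <- t[win]; vw <- v[win]
    ipk <- which.max(vw)
    post <- ipk:length(vw)
    rep_rel <- which(vw[post] <= level)
    if (length(rep_rel)) {
      i2 <- post[rep_rel[1]]
      i1 <- i2 - 1L
      t_rep <- if (i1 >= 1 && vw[i1] > level)
        tw[i1] + (vw[i1] - level) / (vw[i1] - vw[i2]) * (tw[i2] - tw[i1])
      else tw[i2]
      apd <- t_rep - a
      repol <- TRUE
    } else {
      apd <- b - a
      repol <- FALSE
    }
    data.frame(n = k, t_act = a, apd = apd, v_peak = v_peak,
               v_rest = v_rest, repolarized = repol,
               cl = if (k < n) activations[k + 1] - a else NA_real_,
               di = NA_real_)
  })
  out <- do.call(rbind, rows)
  out$di <- out$cl - out$apd
  out
}

#' Local restitution curves along the sampling line
#'
#' For every cell on the recording's sampling line, pairs the cycle length
#' of beat n with the APD of beat n + 1, the construction of the local
#' restitution plots. Cells are labelled border-zone or normal-zone by
#' distance to the scar rim.
#'
#' @param recording \code{\link{run_tissue}} recording with line traces.
#' @param geom \code{\link{tissue_geometry}}.
#' @param l_max link cutoff defining the border-zone annulus (mm).
#' @param margin annulus margin (mm).
#' @param min_apd_beats cells with fewer beats are skipped.
#' @return data.frame: \code{cell} (position along the line), \code{i},
#'   \code{j}, \code{zone}, \code{beat}, \code{cl_n}, \code{apd_next}.
#' @export
restitution_curves <- function(recording, geom, l_max = 2.5,
                               margin = 2 * geom$dx, min_apd_beats = 2) {
  stopifnot(inherits(recording, "tissue_recording"))
  if (is.null(recording$line_v)) stop("recording has no line traces")
  line <- geom$sampling_line
  bz <- border_zone(geom, l_max, margin)
  rows <- list()
  for (c in seq_len(nrow(line))) {
    i <- line[c, 1]; j <- line[c, 2]
    if (geom$scar[i, j]) next
    apds <- compute_apd(recording$line_t, recording$line_v[, c])
    apds <- apds[apds$repolarized | is.na(apds$cl), ]
    if (nrow(apds) < min_apd_beats) next
    nb <- nrow(apds)
    if (nb < 2) next
    rows[[length(rows) + 1L]] <- data.frame(
      cell = c, i = i, j = j,
      zone = if (bz[i, j]) "border" else "normal",
      beat = seq_len(nb - 1),
      cl_n = apds$cl[-nb],
      apd_next = apds$apd[-1], row.names = NULL)
  }
  if (!length(rows))
    return(data.frame(cell = integer(), i = integer(), j = integer(),
                      zone = character(), beat = integer(),
                      cl_n = numeric(), apd_next = numeric()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' APD dispersion at a cycle length
#'
#' Max minus min of APD(n+1) over the sampling-line cells that have a
#' restitution point with CL(n) within \code{tol} of \code{at_cl}.
#' @param curves data.frame from \code{\link{restitution_curves}}.
#' @param at_cl cycle length of interest (ms; the rapid-pacing period).
#' @param tol CL bin half-width (ms).
#' @return dispersion (ms, non-negative).
#' @export
apd_dispersion <- function(curves, at_cl = 300, tol = 5) {
  sel <- curves[!is.na(curves$cl_n) & abs(curves$cl_n - at_cl) <= tol, ]
  if (length(unique(sel$cell)) < 2)
    stop(sprintf("fewer than 2 cells have a beat with CL in %g +/- %g ms",
                 at_cl, tol))
  per_cell <- tapply(sel$apd_next, sel$cell, max)
  max(per_cell) - min(per_cell)
}

#' Space-time section of the sampling line
#'
#' The recorded voltages of the cells along a line, as a time-by-position
#' matrix (exact extraction, no interpolation).
#' @param recording \code{\link{run_tissue}} recording.
#' @param cells optional subset/reordering of line positions.
#' @return numeric matrix, rows = recorded times, columns = positions;
#'   row/column names carry times (ms) and positions.
#' @export
space_time_section <- function(recording, cells = NULL) {
  if (is.null(recording$line_v)) stop("recording has no line traces")
  m <- recording$line_v
  if (!is.null(cells)) m <- m[, cells, drop = FALSE]
  dimnames(m) <- list(format(recording$line_t, trim = TRUE),
                      if (is.null(cells)) seq_len(ncol(m)) else cells)
  m
}

#' Classify a pacing run as NR, BR or PR
#'
#' Codifies the reentry-regime taxonomy: \emph{retrograde activity} is any
#' activation that is (a) late -- more than \code{late_frac} of a pacing
#' period after the incident wavefront was due at that point, with the
#' front timing referenced from the first beat -- and (b) locally
#' retrograde -- the activation-time gradient along the pacing axis
#' opposes the incident direction. The run is \strong{PR} when retrograde
#' activity reaches beyond the border-zone annulus (distance >
#' l_max + margin from the scar rim) or collides with a subsequent pacing
#' wave, \strong{BR} when retrograde activity exists but stays inside the
#' annulus and dies out within the horizon (two pacing periods after the
#' last stimulus), and \strong{NR} otherwise.
#'
#' @param x a \code{tissue_recording}, or an activation-time matrix
#'   (points x beats, NA-padded) for constructed maps.
#' @param geom \code{\link{tissue_geometry}}.
#' @param protocol \code{\link{pacing_protocol}} that produced the run
#'   (pacing from the x = 1 edge).
#' @param l_max link cutoff defining the annulus (mm).
#' @param margin annulus margin (mm; default 2 grid spacings).
#' @param late_frac lateness criterion as a fraction of the period.
#' @param grad_window neighbour activations within this window (ms) are
#'   treated as the same wave passage when estimating the local gradient.
#' @param t_end end of the observation window (ms); taken from the
#'   recording when available.
#' @return object of class \code{"regime_label"}: \code{label} and an
#'   \code{evidence} list (retrograde point/event counts, maximum distance
#'   beyond the rim, collision count, confinement and die-out flags).
#' @export
classify_regime <- function(x, geom, protocol, l_max, margin = 2 * geom$dx,
                            late_frac = 0.5, grad_window = 30,
                            t_end = NULL) {
  if (inherits(x, "tissue_recording")) {
    act <- x$act
    if (is.null(t_end)) t_end <- x$t_end
  } else {
    act <- x
    if (is.null(t_end)) t_end <- max(act, na.rm = TRUE)
  }
  nx <- geom$nx; ny <- geom$ny
  if (nrow(act) != nx * ny) stop("activation log does not match geometry")
  period <- protocol$period
  stim_times <- (seq_len(protocol$n_beats) - 1) * protocol$period
  last_stim <- max(stim_times)
  horizon <- last_stim + 2 * period

  nonscar <- !geom$scar
  if (all(is.na(act[which(nonscar), ])))
    return(structure(list(label = "NR",
                          evidence = list(n_retro_points = 0L,
                                          n_retro_events = 0L,
                                          max_beyond_rim = 0,
                                          n_collisions = 0L,
                                          confined = TRUE,
                                          died_out = TRUE,
                                          quiescent = TRUE)),
                     class = "regime_label"))

  # reference front passage per point, from the first clean beat
  first <- act[, 1]
  front <- first - stim_times[1]
  front[geom$scar] <- NA
  ok_front <- !is.na(front) & front >= 0 & front < period

  if (!any(ok_front))
    stop("no activation coverage to reference the pacing front")

  # all events beyond beat 1
  amat <- matrix(act, nrow = nx * ny)
  retro_pts <- integer(); retro_t <- numeric(); n_coll <- 0L
  dist_rim <- scar_rim_distance(geom, cap = l_max + margin + 20 * geom$dx)
  annulus_r <- l_max + margin

  for (k in seq_len(ncol(amat))) {
    ev <- which(!is.na(amat[, k]) & nonscar[seq_len(nx * ny)])
    for (p in ev) {
      tt <- amat[p, k]
      b <- findInterval(tt, stim_times)
      if (b < 1) next
      if (!ok_front[p]) next
      due <- stim_times[b] + front[p]
      if (tt - due <= late_frac * period) next
      # local gradient along the pacing axis among same-passage neighbours
      ij <- .pt_ij(p, nx)
      i <- ij[1]; j <- ij[2]
      gplus <- gminus <- NA_real_
      if (i < nx && nonscar[i + 1, j]) {
        tn <- amat[.pt_index(i + 1L, j, nx), ]
        tn <- tn[!is.na(tn) & abs(tn - tt) <= grad_window]
        if (length(tn)) gplus <- min(tn) - tt
      }
      if (i > 1 && nonscar[i - 1, j]) {
        tn <- amat[.pt_index(i - 1L, j, nx), ]
        tn <- tn[!is.na(tn) & abs(tn - tt) <= grad_window]
        if (length(tn)) gminus <- tt - min(tn)
      }
      g <- mean(c(gplus, gminus), na.rm = TRUE)
      if (!is.finite(g) || g >= 0) next  # antegrade or undetermined
      retro_pts <- c(retro_pts, p)
      retro_t <- c(retro_t, tt)
      # collision: the next front is due at this point within the window
      if (b < length(stim_times)) {
        due_next <- stim_times[b + 1] + front[p]
        if (abs(tt - due_next) <= grad_window) n_coll <- n_coll + 1L
      }
    }
  }

  if (length(retro_pts) == 0) {
    lab <- "NR"
    evidence <- list(n_retro_points = 0L, n_retro_events = 0L,
                     max_beyond_rim = 0, n_collisions = 0L,
                     confined = TRUE, died_out = TRUE, quiescent = FALSE)
  } else {
    d <- dist_rim[retro_pts]
    beyond <- max(d - annulus_r, 0)
    confined <- all(d <= annulus_r)
    died_out <- if (t_end >= horizon) all(retro_t <= horizon) else
      all(retro_t <= t_end)  # best evidence available
    lab <- if (!confined || n_coll > 0 || !died_out) "PR"
           else "BR"
    evidence <- list(n_retro_points = length(unique(retro_pts)),
                     n_retro_events = length(retro_t),
                     max_beyond_rim = beyond, n_collisions = n_coll,
                     confined = confined, died_out = died_out,
                     quiescent = FALSE)
  }
  structure(list(label = lab, evidence = evidence),
            class = "regime_label")
}

#' @export
print.regime_label <- function(x, ...) {
  e <- x$evidence
  cat(sprintf(paste0("regime: %s (retro points %d, events %d, beyond rim ",
                     "%.2f mm, collisions %d)\n"),
              x$label, e$n_retro_points, e$n_retro_events,
              e$max_beyond_rim, e$n_collisions))
  invisible(x)
}
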