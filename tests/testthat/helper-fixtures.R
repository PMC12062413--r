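# Shared fixtures: small geometries, hand-built link sets, synthetic traces
# and constructed activation maps for the regime classifier.

tiny_geom <- function() tissue_geometry(60, 12, scar_shape = "none")

small_line_geom <- function()
  tissue_geometry(60, 12, scar_shape = "line", scar_cols = 29:33)

# 60 x 60 with a 0.25 cm scar: leaves > 3.5 mm of tissue beyond the
# border-zone annulus, so escape-type reentry maps are constructible
small_circle_geom <- function()
  tissue_geometry(60, 60, scar_shape = "circle", scar_radius_cm = 0.25)

pt_of <- function(geom, i, j) (j - 1L) * geom$nx + i

# a hand-built link set (no generator involved)
manual_links <- function(geom, proximal, distal, gs = 1, l_max = 2.5) {
  structure(list(proximal = as.integer(proximal), distal = distal,
                 n_units = length(proximal), lambda = 0, l_max = l_max,
                 seed = NA_integer_, gs = gs, pool = "manual",
                 realisation = NA_integer_, nx = geom$nx, ny = geom$ny,
                 dx = geom$dx),
            class = "link_set")
}

# square two-pulse trace crossing -40 mV at t = 100 and t = 400
square_two_pulse <- function(dt = 0.5, width = 120) {
  t <- seq(0, 600, by = dt)
  v <- rep(-86, length(t))
  v[t >= 100 & t < 100 + width] <- 20
  v[t >= 400 & t < 400 + width] <- 20
  list(t = t, v = v)
}

# ---- constructed activation maps for classify_regime -----------------------
# Plane pacing from the x = 1 edge at period `period`; front passage at
# point (i, j) is (i - 1) * slow ms after each stimulus.

map_protocol <- function(n_beats = 3, period = 300)
  pacing_protocol("edge", period = period, n_beats = n_beats)

empty_map <- function(geom, n_slots = 8)
  matrix(NA_real_, geom$nx * geom$ny, n_slots)

fill_plane_beats <- function(act, geom, beats, period = 300, slow = 0.5) {
  for (j in seq_len(geom$ny)) for (i in seq_len(geom$nx)) {
    p <- pt_of(geom, i, j)
    if (geom$scar[i, j]) next
    act[p, seq_along(beats)] <- (beats - 1) * period + (i - 1) * slow
  }
  act
}

# plane waves only
map_plane <- function(geom, n_beats = 3) {
  fill_plane_beats(empty_map(geom), geom, seq_len(n_beats))
}

# plane waves with a slow (sub-T/2) detour delay behind the obstacle
map_detour <- function(geom, n_beats = 3) {
  act <- map_plane(geom, n_beats)
  ci <- (geom$nx + 1) / 2
  for (j in seq_len(geom$ny)) for (i in seq_len(geom$nx)) {
    if (geom$scar[i, j] || i <= ci) next
    p <- pt_of(geom, i, j)
    act[p, seq_len(n_beats)] <- act[p, seq_len(n_beats)] + 80  # < T/2
  }
  act
}

# add a retrograde (leftward-propagating) late cluster after beat `after`
# on the mid row, columns `cols`, starting `lateness` ms after the local
# front was due
add_retro_cluster <- function(act, geom, cols, after = 2, period = 300,
                              slow = 0.5, lateness = 200, slot = 6) {
  j0 <- round((geom$ny + 1) / 2)
  base <- (after - 1) * period
  for (i in cols) {
    p <- pt_of(geom, i, j0)
    due <- base + (i - 1) * slow
    # activation time decreases with i => propagating toward -x
    act[p, slot] <- due + lateness + 2 * (max(cols) - i)
  }
  act
}

# columns just outside the scar rim on the distal (+x) side
rim_cols <- function(geom, depth) {
  ci <- (geom$nx + 1) / 2
  rad <- geom$scar_radius_cm * 10 / geom$dx
  first <- ceiling(ci + rad) + 1L
  first:(first + depth - 1L)
}
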