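# Trace analyses (activation detection, APD90, restitution, dispersion,
# space-time sections) and the NR/BR/PR regime classifier on constructed
# activation maps.

test_that("activation detection: crossings, lockout, degenerate traces", {
  sq <- square_two_pulse()
  # sharp edges fall between samples; crossings land within one sample
  expect_equal(detect_activations(sq$t, sq$v), c(100, 400),
               tolerance = 0.5)
  flat <- rep(-86, 100)
  expect_length(detect_activations(seq_along(flat), flat), 0)
  expect_length(detect_activations(sq$t, sq$v, threshold = 50), 0)
  # two crossings inside the lockout collapse to one
  t <- seq(0, 200, by = 0.5)
  v <- rep(-86, length(t))
  v[t >= 50 & t < 60] <- 0
  v[t >= 80 & t < 90] <- 0
  expect_length(detect_activations(t, v, lockout = 50), 1)
  expect_length(detect_activations(t, v, lockout = 20), 2)
})

test_that("APD90 of a sharp square pulse equals its width", {
  sq <- square_two_pulse(width = 120)
  apds <- compute_apd(sq$t, sq$v)
  expect_equal(nrow(apds), 2)
  expect_lt(max(abs(apds$apd - 120)), 1)   # within one sample
  expect_true(all(apds$repolarized))
  expect_equal(apds$cl[1], 300, tolerance = 1e-6)
  expect_equal(apds$di[1], apds$cl[1] - apds$apd[1])
})

test_that("subthreshold responses are not counted as beats", {
  t <- seq(0, 500, by = 0.5)
  v <- rep(-86, length(t))
  v[t >= 100 & t < 300] <- 10    # one real AP
  v[t >= 400 & t < 420] <- -60   # blocked beat: never crosses -40
  apds <- compute_apd(t, v)
  expect_equal(nrow(apds), 1)
})

test_that("steady pacing yields constant APD over the last beats", {
  st <- equilibrate_myocyte()
  r <- run_myocyte(8000, stim_times = (0:7) * 1000, init = st,
                   record_dt = 0.5)
  apds <- compute_apd(r$trace$time, r$trace$v)
  last3 <- tail(apds$apd[apds$repolarized], 3)
  expect_lt(diff(range(last3)), 1)
})

test_that("identical uniformly paced cells give coincident curves and zero dispersion", {
  # synthetic recording: 8 cells share one paced trace
  sq_t <- seq(0, 1300, by = 1)
  v <- rep(-86, length(sq_t))
  for (b in 0:3) v[sq_t >= b * 300 + 10 & sq_t < b * 300 + 10 + 180] <- 15
  g <- tiny_geom()
  ncell <- nrow(g$sampling_line)
  rec <- structure(list(line_t = sq_t,
                        line_v = matrix(v, length(sq_t), ncell),
                        cfg = list(geom = g)),
                   class = "tissue_recording")
  curves <- restitution_curves(rec, g, l_max = 2.5)
  expect_true(all(curves$zone == "normal"))
  spread <- tapply(curves$apd_next, curves$beat, function(x) diff(range(x)))
  expect_true(all(spread == 0))
  expect_equal(apd_dispersion(curves, at_cl = 300), 0)
})

test_that("dispersion is max minus min APD at the cycle-length bin", {
  curves <- data.frame(cell = c(1, 2), i = 1:2, j = 1, zone = "border",
                       beat = 1, cl_n = c(300, 301),
                       apd_next = c(200, 340))
  expect_equal(apd_dispersion(curves, at_cl = 300), 140)
  expect_error(apd_dispersion(curves[1, ], at_cl = 300), "fewer than 2")
  expect_error(apd_dispersion(curves, at_cl = 600), "fewer than 2")
})

test_that("space-time sections are exact extractions", {
  m <- matrix(seq_len(12), 4, 3)
  rec <- structure(list(line_t = 1:4, line_v = m),
                   class = "tissue_recording")
  s <- space_time_section(rec)
  expect_equal(unname(s), m)
  rev_s <- space_time_section(rec, cells = 3:1)
  expect_equal(unname(rev_s), m[, 3:1])
  one <- space_time_section(rec, cells = 2)
  expect_equal(as.numeric(one), m[, 2])
})

# ---- regime classifier on the constructed map library ----------------------

test_that("plane-wave and detour maps classify as NR", {
  g <- small_circle_geom()
  proto <- map_protocol()
  expect_equal(classify_regime(map_plane(g), g, proto, l_max = 2.5,
                               t_end = 900)$label, "NR")
  expect_equal(classify_regime(map_detour(g), g, proto, l_max = 2.5,
                               t_end = 900)$label, "NR")
})

test_that("quiescent maps classify as NR", {
  g <- small_circle_geom()
  lab <- classify_regime(empty_map(g), g, map_protocol(), l_max = 2.5,
                         t_end = 900)
  expect_equal(lab$label, "NR")
  expect_true(lab$evidence$quiescent)
})

test_that("a late retrograde ring confined to the annulus is BR", {
  g <- small_circle_geom()
  act <- map_plane(g)
  act <- add_retro_cluster(act, g, cols = rim_cols(g, 4), after = 2)
  lab <- classify_regime(act, g, map_protocol(), l_max = 2.5, t_end = 1200)
  expect_equal(lab$label, "BR")
  expect_true(lab$evidence$confined)
  expect_gt(lab$evidence$n_retro_points, 0)
})

test_that("retrograde activity escaping the annulus is PR", {
  g <- small_circle_geom()
  act <- map_plane(g)
  # cluster reaching far beyond the rim (annulus is 2.5 mm + margin)
  act <- add_retro_cluster(act, g, cols = rim_cols(g, 14), after = 2)
  lab <- classify_regime(act, g, map_protocol(), l_max = 2.5, t_end = 1200)
  expect_equal(lab$label, "PR")
  expect_false(lab$evidence$confined)
  expect_gt(lab$evidence$max_beyond_rim, 0)
})

test_that("retrograde activity colliding with the next pacing wave is PR", {
  g <- small_circle_geom()
  proto <- map_protocol(n_beats = 3)
  act <- map_plane(g)
  # retrograde events timed to meet the beat-3 front at these points:
  # inside beat 2's window (t < 600) but within the collision window of
  # the beat-3 front due time, with activation times decreasing along +x
  j0 <- round((g$ny + 1) / 2)
  cols <- rim_cols(g, 4)
  for (i in cols) {
    p <- pt_of(g, i, j0)
    due3 <- 600 + (i - 1) * 0.5
    act[p, 6] <- due3 - 25 - 1 * (i - min(cols))
    act[p, 3] <- NA                               # the front never arrives
  }
  lab <- classify_regime(act, g, proto, l_max = 2.5, t_end = 1200)
  expect_equal(lab$label, "PR")
  expect_gt(lab$evidence$n_collisions, 0)
})

test_that("classification is deterministic and needs front coverage", {
  g <- small_circle_geom()
  act <- map_plane(g)
  act <- add_retro_cluster(act, g, cols = rim_cols(g, 4), after = 2)
  a <- classify_regime(act, g, map_protocol(), l_max = 2.5, t_end = 1200)
  b <- classify_regime(act, g, map_protocol(), l_max = 2.5, t_end = 1200)
  expect_identical(a, b)
  # an all-NA first beat means the pacing front cannot be referenced
  broken <- empty_map(g)
  broken[pt_of(g, 3, 3), 2] <- 500
  expect_error(classify_regime(broken, g, map_protocol(), l_max = 2.5,
                               t_end = 900), "front")
})
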