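# Pacing protocols, the sweep enumeration/resume logic and the line-scar
# conduction test at reduced scale.

test_that("the study sweep enumerates exactly 180 runs", {
  g <- sweep_grid(sweep_spec())
  expect_equal(nrow(g), 180)
  expect_equal(nrow(unique(g[, 1:4])), 180)
  # Cartesian structure: every axis value appears the same number of times
  expect_true(all(table(g$lambda) == 60))
  expect_true(all(table(g$n_units) == 60))
  expect_true(all(table(g$gs) == 45))
  expect_true(all(table(g$realisation) == 36))
})

test_that("degenerate sweep specs enumerate their product", {
  one <- sweep_spec(lambda = 50, n_units = 1000, realisations = 1, gs = 2)
  expect_equal(nrow(sweep_grid(one)), 1)
  two <- sweep_spec(lambda = c(40, 50), n_units = 1000, realisations = 1:2,
                    gs = 3)
  expect_equal(nrow(sweep_grid(two)), 4)
})

test_that("marginal regime fractions partition to one", {
  res <- data.frame(lambda = rep(c(40, 50), each = 6),
                    n_units = 1000, realisation = 1, gs = 1,
                    label = c("NR", "NR", "BR", "PR", "NR", "PR",
                              "NR", "BR", "BR", "NR", "PR", "NR"))
  fr <- regime_fractions(res, "lambda")
  sums <- tapply(fr$fraction, fr$lambda, sum)
  expect_equal(as.numeric(sums), c(1, 1))
  expect_equal(fr$fraction[fr$lambda == 40 & fr$label == "NR"], 3 / 6)
})

test_that("run_sweep runs the grid and resumes completed rows", {
  g <- small_circle_geom()
  spec <- sweep_spec(lambda = 10, n_units = 50, realisations = 1:2, gs = 1)
  calls <- new.env(); calls$n <- 0
  stub <- function(cfg, protocol) {
    calls$n <- calls$n + 1
    list(regime = list(label = "NR"))
  }
  csv <- tempfile(fileext = ".csv")
  r1 <- run_sweep(spec, g, out_csv = csv, runner = stub, verbose = FALSE)
  expect_equal(nrow(r1), 2)
  expect_equal(calls$n, 2)
  expect_true(all(r1$label == "NR"))
  # resume: nothing new is executed
  r2 <- run_sweep(spec, g, out_csv = csv, runner = stub, verbose = FALSE)
  expect_equal(calls$n, 2)
  expect_equal(r2$label, r1$label)
})

test_that("individual run failures are recorded and the sweep continues", {
  g <- small_circle_geom()
  spec <- sweep_spec(lambda = 10, n_units = 50, realisations = 1:2, gs = 1)
  boom <- function(cfg, protocol) stop("numerical blow-up")
  res <- run_sweep(spec, g, runner = boom, verbose = FALSE)
  expect_equal(nrow(res), 2)
  expect_true(all(is.na(res$label)))
  expect_match(res$error[1], "blow-up")
})

test_that("edge and point stimuli cover the intended regions", {
  g <- tiny_geom()
  edge <- fibrolink:::.protocol_stimulus(pacing_protocol("edge",
                                                         n_beats = 3), g)
  expect_equal(length(edge$idx), 3 * g$ny)
  expect_equal(edge$times, c(0, 300, 600))
  pts <- fibrolink:::.protocol_stimulus(
    pacing_protocol("point", site = c(10, 6), n_beats = 1), g)
  expect_equal(length(pts$idx), 25)
  s1s2 <- fibrolink:::.protocol_stimulus(
    pacing_protocol("s1s2", n_beats = 2, s2_interval = 150), g)
  expect_equal(s1s2$times, c(0, 300, 450))
  none <- fibrolink:::.protocol_stimulus(pacing_protocol("none"), g)
  expect_equal(length(none$idx), 0)
})

test_that("zero coupling cannot conduct across the line scar", {
  r <- line_scar_conduction_test(gs = 0, nf = 8, geom = small_line_geom(),
                                 duration = 300)
  expect_false(r$conducted)
  expect_true(is.na(r$delay))
  # the wave did arrive at the proximal flank
  g <- small_line_geom()
  left <- min(g$scar_cols) - 2L
  expect_true(any(r$recording$n_act[pt_of(g, rep(left, g$ny),
                                          seq_len(g$ny))] > 0))
})

test_that("conduction threshold behaviour on the reduced strip", {
  # the compact version of the line-scar calibration: weak coupling blocks,
  # strong coupling conducts with a positive trans-scar delay
  blocked <- line_scar_conduction_test(gs = 2, nf = 8,
                                       geom = small_line_geom(),
                                       duration = 400)
  expect_false(blocked$conducted)
  conducted <- line_scar_conduction_test(gs = 4, nf = 8,
                                         geom = small_line_geom(),
                                         duration = 400)
  expect_true(conducted$conducted)
  expect_gt(conducted$delay, 0)
})

test_that("protocol validation", {
  expect_error(pacing_protocol(period = 0), "period")
  expect_error(pacing_protocol(n_beats = 0), "n_beats")
  expect_error(pacing_protocol("s1s2"), "s2_interval")
})
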