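# Monodomain solver: diffusion operator, coupling exactness, conservation,
# symmetry and determinism.

test_that("diffusion of a uniform field is identically zero", {
  g <- small_line_geom()
  v <- matrix(-86.2, g$nx, g$ny)
  expect_true(all(diffusion_term(v, g) == 0))
})

test_that("no-flux diffusion conserves total voltage for any field", {
  g <- small_line_geom()
  set.seed(1)
  v <- matrix(rnorm(g$nx * g$ny, -60, 30), g$nx, g$ny)
  lap <- diffusion_term(v, g)
  expect_lt(abs(sum(lap)), 1e-9)
  # and no flux enters the scar: scar points see zero diffusion
  expect_true(all(lap[g$scar] == 0))
})

test_that("1D Gaussian spreads like the analytic heat kernel", {
  g <- tissue_geometry(120, 8, scar_shape = "none")
  d_mm2 <- g$d_reg * 100
  x <- (seq_len(g$nx) - 60.5) * g$dx
  s0 <- 2.0
  v <- matrix(rep(exp(-x^2 / (2 * s0^2)), g$ny), g$nx, g$ny)
  dt <- 0.01; nsteps <- 1000  # 10 ms
  for (k in seq_len(nsteps)) v <- v + dt * diffusion_term(v, g)
  prof <- v[, 4]
  s2_num <- sum(prof * x^2) / sum(prof)
  s2_ref <- s0^2 + 2 * d_mm2 * nsteps * dt
  expect_lt(abs(s2_num - s2_ref) / s2_ref, 0.01)
})

test_that("the C++ field update reproduces the R diffusion operator", {
  g <- small_line_geom()
  set.seed(2)
  v0 <- matrix(rnorm(g$nx * g$ny, -70, 10), g$nx, g$ny)
  npts <- g$nx * g$ny
  myo0 <- matrix(rep(unname(myocyte_initial_state()), each = npts),
                 npts, 19)
  myo0[, 1] <- as.vector(v0)
  out <- fibrolink:::cpp_run_tissue(
    g$nx, g$ny, as.integer(g$scar), g$d_reg * 100, g$dx,
    unclass(myocyte_params()), unclass(fibroblast_params()),
    myo0, matrix(0, 0, 3), 0L, integer(), 0, FALSE, 0, 0.01, 1L,
    numeric(), 0, 0, integer(), integer(), 0L, 0L, -40, 50, 1L,
    integer(), FALSE, TRUE, FALSE, TRUE)  # freeze_myo_ion = TRUE
  got <- (matrix(out$final_myo[, 1], g$nx, g$ny) - v0) / 0.01
  expect_lt(max(abs(got - diffusion_term(v0, g))), 1e-9)
})

test_that("resting tissue without stimulus or links stays put", {
  g <- tissue_geometry(20, 8, scar_shape = "none")
  cfg <- sim_config(g, duration = 1, snapshot_dt = 0, line_dt = 1,
                    equilibrate_ms = 0)
  rec <- run_tissue(cfg)   # 100 steps
  v <- rec$final$myo[, 1]
  expect_lt(max(abs(v - v[1])), 1e-12)        # stays spatially uniform
  expect_lt(max(abs(v - rec$line_v[1, 1])), 1e-3)  # and near rest
})

test_that("a single link relaxes to the two-capacitor closed form", {
  # D = 0, frozen ionic currents on both sides: pure linear exchange
  g <- tissue_geometry(3, 3, scar_shape = "none", d_reg = 0)
  npts <- 9; gs <- 4; nf <- 8; cm <- 150; cf <- 50
  myo0 <- matrix(rep(unname(myocyte_initial_state()), each = npts),
                 npts, 19)
  v0 <- -80; vf0 <- -20
  myo0[, 1] <- v0
  fib0 <- matrix(c(vf0, 0.05, 0.9), 1, 3)
  nsteps <- 20000L; dt <- 0.01
  out <- fibrolink:::cpp_run_tissue(
    g$nx, g$ny, as.integer(g$scar), 0, g$dx,
    unclass(myocyte_params()), unclass(fibroblast_params(nf = nf)),
    myo0, fib0, c(0L, 1L), 4L, gs, FALSE, 0, dt, nsteps,
    numeric(), 0, 0, integer(), 5L - 1L, 10L, 0L, -40, 50, 1L,
    integer(), FALSE, TRUE, TRUE, TRUE)  # freeze both ionic currents
  # closed form: dV/dt = nf gs (Vf - V)/Cm ; dVf/dt = gs (V - Vf)/Cf
  k <- nf * gs / cm + gs / cf
  t <- out$line_t
  vinf <- (cm * v0 + nf * cf * vf0) / (cm + nf * cf)
  v_ref <- vinf + (v0 - vinf) * exp(-k * t)
  # forward Euler vs the exact exponential: O(dt) bias ~ dV k dt / 2
  expect_lt(max(abs(out$line_v[, 1] - v_ref)), 0.05)
  # monotone approach and conserved weighted charge
  expect_true(all(diff(out$line_v[, 1]) >= 0))
  q0 <- cm * v0 + nf * cf * vf0
  q1 <- cm * out$final_myo[5, 1] + nf * cf * out$final_fib[1, 1]
  expect_lt(abs(q1 - q0) / abs(q0), 1e-9)
})

test_that("an inactive scar point with one link is a passive RC node", {
  g <- tissue_geometry(5, 5, scar_shape = "line", scar_cols = 3)
  npts <- 25; gs <- 2; cm <- 150
  myo0 <- matrix(rep(unname(myocyte_initial_state()), each = npts),
                 npts, 19)
  myo0[, 1] <- -86
  # one enormous fibroblast: its voltage is effectively clamped
  fib0 <- matrix(c(-20, 0.05, 0.9), 1, 3)
  fp <- fibroblast_params(nf = 1, cf = 1e9)
  p_scar <- pt_of(g, 3, 3)
  out <- fibrolink:::cpp_run_tissue(
    g$nx, g$ny, as.integer(g$scar), g$d_reg * 100, g$dx,
    unclass(myocyte_params()), unclass(fp),
    myo0, fib0, c(0L, 1L), p_scar - 1L, gs, TRUE, 0, 0.01, 50000L,
    numeric(), 0, 0, integer(), p_scar - 1L, 100L, 0L, -40, 50, 1L,
    integer(), FALSE, FALSE, TRUE, TRUE)
  tau <- cm / gs   # 75 ms
  t <- out$line_t
  v_ref <- -20 + (-86 + 20) * exp(-t / tau)
  expect_lt(max(abs(out$line_v[, 1] - v_ref)), 0.05)
})

test_that("coupling charge is antisymmetric at field scale", {
  g <- small_line_geom()
  links <- make_line_scar_links(g)
  cfg <- sim_config(g, links, gs = 4, nf = 8, duration = 80,
                    snapshot_dt = 0, line_dt = 0, equilibrate_ms = 20)
  rec <- run_tissue(cfg, pacing_protocol("edge", n_beats = 1))
  expect_lt(rec$balance_max, 1e-6)  # pA, over every step of the run
})

test_that("identical configurations give bit-identical recordings", {
  g <- small_line_geom()
  links <- make_line_scar_links(g)
  cfg <- sim_config(g, links, gs = 3, nf = 8, duration = 60,
                    snapshot_dt = 20, line_dt = 1, equilibrate_ms = 10)
  r1 <- run_tissue(cfg, pacing_protocol("edge", n_beats = 1))
  r2 <- run_tissue(cfg, pacing_protocol("edge", n_beats = 1))
  expect_identical(r1$line_v, r2$line_v)
  expect_identical(r1$snaps, r2$snaps)
  expect_identical(r1$act, r2$act)
})

test_that("mirror-symmetric runs stay mirror-symmetric", {
  g <- small_line_geom()
  links <- make_line_scar_links(g)  # symmetric about the mid row
  cfg <- sim_config(g, links, gs = 4, nf = 8, duration = 120,
                    snapshot_dt = 0, line_dt = 0, equilibrate_ms = 20)
  rec <- run_tissue(cfg, pacing_protocol("edge", n_beats = 1))
  v <- matrix(rec$final$myo[, 1], g$nx, g$ny)
  expect_lt(max(abs(v - v[, rev(seq_len(g$ny))])), 1e-9)
})

test_that("0-duration run echoes the initial state", {
  g <- tiny_geom()
  cfg <- sim_config(g, duration = 0, snapshot_dt = 0, line_dt = 0,
                    equilibrate_ms = 0)
  st <- equilibrate_myocyte()
  rec <- run_tissue(cfg)
  expect_equal(rec$final$myo[1, ], unname(st), tolerance = 1e-12)
  expect_equal(rec$t_end, 0)
})

test_that("unstable configurations are rejected up front", {
  g <- tissue_geometry(20, 8, scar_shape = "none", d_reg = 0.01)
  expect_error(sim_config(g, dt = 0.05), "unstable")
})

test_that("stepping interface advances states like a single run", {
  g <- tissue_geometry(20, 6, scar_shape = "none")
  cfg <- sim_config(g, duration = 10, snapshot_dt = 0, line_dt = 0,
                    equilibrate_ms = 0)
  full <- run_tissue(cfg, pacing_protocol("edge", n_beats = 1))
  st <- list(myo = matrix(rep(unname(equilibrate_myocyte()),
                              each = 120), 120, 19),
             fib = matrix(0, 0, 3))
  s1 <- step_tissue(cfg, st, n_steps = 500,
                    protocol = pacing_protocol("edge", n_beats = 1))
  s2 <- step_tissue(cfg, s1, n_steps = 500,
                    protocol = pacing_protocol("edge", n_beats = 1), t0 = 5)
  expect_equal(s2$myo[, 1], full$final$myo[, 1], tolerance = 1e-9)
})
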