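# Unit tests for the TP06 myocyte and MacCannell fibroblast models.

test_that("IK1 vanishes at the potassium reversal potential", {
  st <- myocyte_initial_state()
  ek <- 26.713760659696 * log(5.4 / st[["ki"]])
  st[["v"]] <- ek
  cur <- myocyte_currents(st)
  expect_lt(abs(cur$i_k1), 1e-10)
  # all other K currents driven by (V - EK) vanish too
  expect_lt(abs(cur$i_to), 1e-10)
  expect_lt(abs(cur$i_kr), 1e-10)
  expect_lt(abs(cur$i_pk), 1e-10)
})

test_that("gated currents vanish with closed gates and zero backgrounds", {
  p <- myocyte_params(gbna = 0, gbca = 0)
  st <- myocyte_initial_state()
  st[c("m", "xr1", "xs", "r", "d")] <- 0
  cur <- myocyte_currents(st, p)
  expect_identical(cur$i_na, 0)
  expect_identical(cur$i_to, 0)
  expect_identical(cur$i_kr, 0)
  expect_identical(cur$i_ks, 0)
  expect_identical(cur$i_cal, 0)
  expect_identical(cur$i_bna, 0)
  expect_identical(cur$i_bca, 0)
})

test_that("non-finite state is rejected naming the variable", {
  st <- myocyte_initial_state()
  st[["cai"]] <- NaN
  expect_error(myocyte_currents(st), "cai")
  stf <- fibroblast_initial_state()
  stf[["vf"]] <- Inf
  expect_error(fibroblast_currents(stf), "vf")
})

test_that("quiescent myocyte holds its rest for 10 s", {
  r <- run_myocyte(10000, record_dt = 100)
  expect_lt(max(abs(r$trace$v - r$trace$v[1])), 0.5)
  # and the equilibrated state carries a tiny net membrane current
  cur <- myocyte_currents(r$final_myo)
  expect_lt(abs(cur$i_ion), 1e-3)
})

test_that("gates stay in [0, 1] along paced trajectories", {
  st <- equilibrate_myocyte()
  gates <- c("m", "h", "j", "xr1", "xr2", "xs", "r", "s", "d", "f",
             "f2", "fcass")
  for (cl in c(1000, 320)) {
    r <- run_myocyte(3 * cl, stim_times = (0:2) * cl, init = st,
                     record_dt = 0.5, record_states = TRUE)
    g <- r$states[, gates]
    expect_gte(min(g), 0)
    expect_lte(max(g), 1)
  }
})

test_that("halving dt changes the single-cell APD by < 1 ms", {
  st <- equilibrate_myocyte()
  apd_at <- function(dt) {
    r <- run_myocyte(600, stim_times = 20, init = st, dt = dt,
                     record_dt = 0.25)
    compute_apd(r$trace$time, r$trace$v)$apd[1]
  }
  expect_lt(abs(apd_at(0.01) - apd_at(0.005)), 1)
})

test_that("table-accelerated stepping matches direct evaluation", {
  st <- equilibrate_myocyte()
  direct <- run_myocyte(400, stim_times = 20, init = st, record_dt = 1)
  tabled <- run_myocyte(400, stim_times = 20, init = st, record_dt = 1,
                        use_tables = TRUE)
  expect_lt(max(abs(direct$trace$v - tabled$trace$v)), 0.05)
})

test_that("coupling current is the direct conductance-gradient product", {
  expect_identical(coupling_current(-80, -80, 4), 0)
  expect_identical(coupling_current(-80, -30, 4), 200)
  expect_identical(coupling_current(13.7, -55.2, 0), 0)
  expect_equal(coupling_current(-80, -30, 4),
               -coupling_current(-30, -80, 4))
  expect_error(coupling_current(-80, -30, -1), "non-negative")
})

test_that("fibroblast IK1 vanishes at its reversal potential", {
  p <- fibroblast_params("native")
  ek <- 26.713760659696 * log(p$ko / p$ki)
  st <- fibroblast_initial_state(p, vf = ek)
  cur <- fibroblast_currents(st, p)
  expect_lt(abs(cur$i_k1), 1e-10)
  expect_lt(abs(cur$i_kv), 1e-10)
})

test_that("calibrated fibroblast variants settle to their targets", {
  # the frozen Kv shifts must reproduce -24.5 / -49.0 mV on re-simulation
  v_dep <- fibroblast_resting_potential(fibroblast_params("depolarized"))
  v_hyp <- fibroblast_resting_potential(fibroblast_params("hyperpolarized"))
  expect_lt(abs(v_dep - (-24.5)), 0.1)
  expect_lt(abs(v_hyp - (-49.0)), 0.1)
})

test_that("fibroblast unit is quiescent at its calibrated rest", {
  r <- run_fibroblast(10000, params = fibroblast_params("depolarized"))
  expect_lt(max(abs(r$trace$vf - r$trace$vf[1])), 0.5)
})

test_that("steady fibroblast rest is monotone in the Kv shift", {
  rests <- vapply(c(0, 15, 30), function(sh)
    fibroblast_resting_potential(fibroblast_params("native", kv_shift = sh),
                                 settle_ms = 5000),
    numeric(1))
  expect_true(all(diff(rests) > 0))
})

test_that("vfr calibration is self-consistent and flags unreachable targets", {
  # identity case: calibrating to the native rest returns a near-zero shift
  native <- fibroblast_resting_potential(fibroblast_params("native"),
                                         settle_ms = 5000)
  sh <- calibrate_vfr_shift(native, settle_ms = 5000)
  expect_lt(abs(sh), 1.5)
  expect_error(calibrate_vfr_shift(-59.9, settle_ms = 2000,
                                   bracket = c(0, 10)),
               "unreachable")
  expect_error(calibrate_vfr_shift(-5), "target_vfr")
})

test_that("S1S2 plateau recovers the steady S1 APD and flags lost capture", {
  res <- s1s2_restitution(n_s1 = 6, s2_intervals = c(900, 150),
                          equilibrate_ms = 500)
  long <- res$curve[res$curve$s2_interval == 900, ]
  expect_true(long$captured)
  expect_lt(abs(long$apd - res$s1_apd), 2)
  short <- res$curve[res$curve$s2_interval == 150, ]
  expect_false(short$captured)   # flagged, not dropped
  expect_true(is.na(short$apd))
})
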