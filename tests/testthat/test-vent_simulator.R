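test_that("jitter series is stationary AR(1) with the requested moments", {
  expect_equal(pip_jitter_series(10, 0.5, 0), rep(0, 10))
  w <- pip_jitter_series(1e5, 0, 1, seed = 3)
  expect_equal(stats::sd(w), 1, tolerance = 0.02)
  b <- pip_jitter_series(1e4, 0.6, 1, seed = 11)
  expect_equal(stats::sd(b), 1 / sqrt(1 - 0.36), tolerance = 0.05)
  expect_error(pip_jitter_series(10, 1, 1), "\\[0, 1\\)")
  expect_error(pip_jitter_series(10, -0.1, 1), "\\[0, 1\\)")
  # deterministic, and leaves the caller's RNG stream untouched
  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(pip_jitter_series(100, 0.5, 1, seed = 77))
  after <- rnorm(1)
  expect_identical(before, after)
  expect_identical(pip_jitter_series(100, 0.5, 1, seed = 77),
                   pip_jitter_series(100, 0.5, 1, seed = 77))
})

test_that("source pressure follows the first-order rise and decay", {
  tb <- vent_source_params("turbine", tau_up = 0.25, tau_down = 0.25)
  # at the end of a 0.75 s inspiration from PEEP: 95.0% of the step
  p <- source_pressure(0.75 - 1e-12, tb, PIP_k = 11, P_start = 3)
  expect_equal(p, 11 - 8 * exp(-3), tolerance = 1e-6)
  # tau_up -> 0: mid-inspiration sits exactly at PIP_k
  sq <- vent_source_params("square", tau_up = 1e-9, tau_down = 1e-9)
  expect_equal(source_pressure(0.4, sq, PIP_k = 11), 11)
  # cycle start in square mode: continuity from expiration at PEEP_set
  expect_equal(source_pressure(0, sq), 3)
  expect_error(source_pressure(2, tb), "t_in_cycle")
})

test_that("a closed pressure gradient delivers no volume", {
  src <- quiet_sim("square", PIP_set = 5, PEEP_set = 5)
  sim <- simulate_vent(lung_params(), src, 10)
  expect_equal(max(abs(sim$flow$v)), 0)
  expect_equal(max(abs(sim$breaths$V_T)), 0)
})

test_that("square-mode equilibration delivers V_T = C * (PIP - PEEP)", {
  sim <- simulate_vent(lung_params(C = 2, R = 0.02),
                       quiet_sim("square"), 62)
  expect_equal(mean(sim$breaths$V_T), 16, tolerance = 0.02)
  br <- segment_breaths(sim$flow)
  expect_equal(sum(br$t_start < 60), sum(sim$breaths$t_start < 60))
})

test_that("the stability guard rejects an unresolvable lung time constant", {
  expect_error(
    simulate_vent(lung_params(C = 0.1, R = 0.05),
                  vent_source_params("square", rate = 100), 10),
    "increase rate")
})

test_that("simulations are bit-identical given the seed", {
  a <- simulate_vent(lung_params(), vent_source_params("turbine", seed = 7), 10)
  b <- simulate_vent(lung_params(), vent_source_params("turbine", seed = 7), 10)
  expect_identical(a$flow$v, b$flow$v)
  expect_identical(a$insp_pressure$v, b$insp_pressure$v)
  expect_identical(a$breaths, b$breaths)
  c <- simulate_vent(lung_params(), vent_source_params("turbine", seed = 8), 10)
  expect_false(identical(a$flow$v, c$flow$v))
})

test_that("volume is conserved over steady-state cycles", {
  for (mode in c("square", "turbine")) {
    sim <- simulate_vent(lung_params(), quiet_sim(mode), 31)
    ss <- sim$breaths[5:nrow(sim$breaths), ]
    expect_lt(max(abs(ss$V_T / ss$V_exp - 1)), 0.01)
  }
})

test_that("clean-pressure PIP recovery matches the per-breath ground truth", {
  sim <- simulate_vent(lung_params(), vent_source_params("square", seed = 4),
                       31)
  gt <- sim$breaths
  pp <- vapply(seq_len(nrow(gt)), function(i) {
    pip_peep(sim$common_pressure, gt$t_start[i], gt$t_insp_end[i],
             gt$t_end[i])["PIP"]
  }, 0)
  expect_lt(max(abs(pp - gt$PIP_true)), 0.1)
  # in square mode the achieved peak also reaches the jittered target
  expect_lt(max(abs(gt$PIP_true - gt$PIP_target)), 0.05)
})

test_that("compliance is recoverable from analyzed simulator output", {
  sim <- simulate_vent(lung_params(), vent_source_params("square", seed = 6),
                       62)
  br <- analyze_breaths(sim$flow, sim$common_pressure)
  C_hat <- mean(br$V_T) / (mean(br$PIP) - mean(br$PEEP))
  expect_equal(C_hat, 2, tolerance = 0.05)
})

test_that("square plateaus 3x longer above 90% of PIP than turbine", {
  frac_above <- function(sim) {
    gt <- sim$breaths
    mean(vapply(seq_len(nrow(gt)), function(k) {
      sel <- sim$common_pressure$t >= gt$t_start[k] &
        sim$common_pressure$t < gt$t_end[k]
      thr <- gt$PEEP_set[k] + 0.9 * (gt$PIP_true[k] - gt$PEEP_set[k])
      mean(sim$common_pressure$v[sel] >= thr)
    }, 0))
  }
  sq <- simulate_vent(lung_params(), quiet_sim("square"), 31)
  tb <- simulate_vent(lung_params(), quiet_sim("turbine"), 31)
  expect_gt(frac_above(sq) / frac_above(tb), 3)
})

test_that("simulation files round-trip through the readers", {
  sim <- simulate_vent(lung_params(), vent_source_params("square", seed = 9),
                       10)
  dir <- withr::local_tempdir()
  write_simulation(sim, dir, prefix = "rt")
  fl <- read_flow_csv(file.path(dir, "rt_flow.csv"), units = "mL/s")
  expect_equal(fl$v, sim$flow$v, tolerance = 1e-7)
  pr <- read_pressure_csv(file.path(dir, "rt_pressure_insp.csv"),
                          units = "cmH2O_gauge")
  expect_equal(pr$v, sim$insp_pressure$v, tolerance = 1e-7)
  expect_true(file.exists(file.path(dir, "rt_provenance.json")))
})
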