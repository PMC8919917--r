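test_that("square flow segments into the scheduled breaths", {
  # 21 onsets -> 20 complete breaths (the trailing cycle has no next onset)
  fl <- square_flow(n_cycles = 21, amp = 100, t_on = 0.75, t_off = 0.75)
  br <- segment_breaths(fl)
  expect_equal(nrow(br), 20)
  expect_true(all(abs(br$T_insp - 0.75) <= 0.011))
  expect_true(all(abs(br$T_exp - 0.75) <= 0.011))
  expect_true(all(abs(br$RR_inst - 40) <= 0.5))
})

test_that("zero flow yields zero breaths, not an error", {
  fl <- const_trace(0, duration = 60, rate = 100, channel = "flow",
                    units = "mL/s")
  br <- segment_breaths(fl)
  expect_equal(nrow(br), 0)
})

test_that("segmentation needs a uniform grid of at least 50 Hz", {
  tt <- c(seq(0, 1, 0.01), seq(1.05, 2, 0.05))
  fl <- waveform_trace(tt, rep(0, length(tt)), "flow")
  expect_error(segment_breaths(fl), "uniform")
  fl2 <- const_trace(0, duration = 10, rate = 20, channel = "flow",
                     units = "mL/s")
  expect_error(segment_breaths(fl2), "50 Hz")
})

test_that("cycles shorter than the minimum are discarded", {
  # 100 ms blips: onset + immediate reversal, 0.1 s cycle < 0.2 s minimum
  fl <- square_flow(n_cycles = 10, amp = 100, t_on = 0.05, t_off = 0.05)
  br <- segment_breaths(fl)
  expect_equal(nrow(br), 0)
})

test_that("per-breath identities hold exactly", {
  fl <- square_flow(n_cycles = 8, t_on = 0.6, t_off = 0.9)
  br <- segment_breaths(fl)
  expect_equal(br$IE * br$T_exp, br$T_insp)
  expect_equal(br$RR_inst * (br$T_insp + br$T_exp), rep(60, nrow(br)))
})

test_that("tidal volume integrates inspiratory flow", {
  fl <- square_flow(n_cycles = 3, amp = 100, t_on = 0.75, t_off = 0.75)
  br <- segment_breaths(fl)
  # rectangle: 100 mL/s x 0.75 s = 75 mL
  expect_equal(tidal_volume(fl, br$t_start[1], br$t_start[1] + 0.75), 75,
               tolerance = 0.02)
  # triangle 0 -> 200 -> 0 over 0.5 s = 50 mL
  tt <- seq(0, 0.5, by = 0.01)
  tri <- waveform_trace(tt, 200 * (1 - abs(tt - 0.25) / 0.25), "flow")
  expect_equal(tidal_volume(tri, 0, 0.5), 50, tolerance = 0.5)
  # zero flow -> 0 mL
  z <- const_trace(0, duration = 2, channel = "flow", units = "mL/s")
  expect_equal(tidal_volume(z, 0.2, 1), 0)
  expect_error(tidal_volume(fl, -1, 0.5), "outside trace support")
})

test_that("PIP and PEEP come from the cycle maximum and expiratory tail", {
  p <- const_trace(7, duration = 3)
  expect_equal(pip_peep(p, 0, 0.75, 1.5), c(PIP = 7, PEEP = 7))
  tt <- seq(0, 3, by = 0.01)
  sq <- waveform_trace(tt, ifelse(tt %% 1.5 < 0.75, 11, 3), "pressure",
                       units = "cmH2O")
  expect_equal(pip_peep(sq, 0, 0.75, 1.5), c(PIP = 11, PEEP = 3))
  short <- waveform_trace(c(0, 1, 2), c(1, 2, 3), "pressure",
                          units = "cmH2O")
  expect_error(pip_peep(short, 0, 0.4, 0.9), "fewer than 3")
})

test_that("simulator PIP_k ground truth is recovered from clean pressure", {
  sim <- simulate_vent(lung_params(), vent_source_params("turbine", seed = 2),
                       31)
  gt <- sim$breaths
  pp <- vapply(seq_len(nrow(gt)), function(i) {
    pip_peep(sim$common_pressure, gt$t_start[i], gt$t_insp_end[i],
             gt$t_end[i])["PIP"]
  }, 0)
  expect_lt(max(abs(pp - gt$PIP_true)), 0.1)
})

test_that("protocol windows follow the 10-min schedule", {
  w <- protocol_windows(61 * 60)
  expect_equal(nrow(w), 7)
  expect_equal(w$start, (0:6) * 600)
  expect_equal(nrow(protocol_windows(5 * 60)), 1)
  expect_error(protocol_windows(30), "argument error")
})

test_that("window summaries compute the protocol arithmetic", {
  br <- data.frame(
    t_start = seq(0, by = 1.5, length.out = 40),
    t_insp_end = seq(0.75, by = 1.5, length.out = 40),
    t_end = seq(1.5, by = 1.5, length.out = 40),
    T_insp = 0.75, T_exp = 0.75, IE = 1, RR_inst = 40,
    V_T = 7.5, PIP = 11.5, PEEP = 2.7
  )
  s <- summarize_window(br, vent_settings(), mass = 3, 0, 60)
  expect_equal(s$mean_V_T_per_kg, 2.5)
  expect_equal(s$minute_ventilation, 100)     # 40 x 7.5 / 1 min / 3 kg
  expect_equal(s$dPIP, 0.5)                   # 11.5 - 11
  expect_equal(s$dPEEP, -0.3)                 # 2.7 - 3
  expect_equal(s$n_breaths, 40L)
  expect_false(s$empty)
})

test_that("summaries are invariant to breath order and flag empty windows", {
  br <- data.frame(
    t_start = c(0, 10, 20), t_insp_end = c(0.7, 10.7, 20.7),
    t_end = c(1.5, 11.5, 21.5), T_insp = 0.7, T_exp = 0.8,
    IE = 0.875, RR_inst = 40, V_T = c(5, 6, 7),
    PIP = c(11, 11.5, 12), PEEP = c(3, 3, 3)
  )
  s1 <- summarize_window(br, vent_settings(), 3, 0, 60)
  s2 <- summarize_window(br[c(3, 1, 2), ], vent_settings(), 3, 0, 60)
  expect_equal(s1, s2)
  s3 <- summarize_window(br, vent_settings(), 3, 120, 60)
  expect_true(s3$empty)
  expect_equal(s3$n_breaths, 0L)
  # straddling breaths belong to no window
  s4 <- summarize_window(br, vent_settings(), 3, 0, 11)
  expect_equal(s4$n_breaths, 1L)
})

test_that("breath counts and metrics recover simulator ground truth", {
  for (seed in c(1, 2)) {
    sim <- simulate_vent(lung_params(),
                         vent_source_params("square", seed = seed), 62)
    br <- analyze_breaths(sim$flow, sim$common_pressure)
    # every complete steady-state minute holds the set number of cycles
    expect_equal(sum(br$t_start < 60), sum(sim$breaths$t_start < 60))
    expect_equal(mean(br$V_T), mean(sim$breaths$V_T), tolerance = 0.02)
    expect_lt(abs(mean(br$RR_inst) - 40), 0.5)
  }
})

test_that("measured I:E contrasts square and turbine sources as expected", {
  sq <- simulate_vent(lung_params(), vent_source_params("square", seed = 3),
                      62)
  bsq <- segment_breaths(sq$flow)
  expect_gt(mean(bsq$IE), 0.95)
  expect_lt(mean(bsq$IE), 1.05)
  tb <- simulate_vent(lung_params(),
                      vent_source_params("turbine", tau_up = 0.25,
                                         tau_down = 0.25, seed = 3), 62)
  btb <- segment_breaths(tb$flow)
  expect_lt(mean(btb$IE), 0.9)
})
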