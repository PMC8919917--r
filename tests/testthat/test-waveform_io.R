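test_that("waveform_trace enforces its invariants", {
  expect_error(waveform_trace(c(0, 0.1), c(1, 2, 3), "flow"), "length")
  expect_error(waveform_trace(0.5, 1, "flow"), "at least 2")
  expect_error(waveform_trace(c(0, 0.2, 0.1), c(1, 2, 3), "flow"),
               "index 3")
  tr <- waveform_trace(c(0, 0.01), c(1, 2), "flow")
  expect_s3_class(tr, "waveform_trace")
  expect_identical(tr$units, "mL/s")
})

test_that("flow reader converts slm to mL/s and re-zeroes time", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time,flow", "10.0,6.0", "10.1,0.0", "10.2,3.0"), path)
  tr <- read_flow_csv(path, units = "slm")
  expect_equal(tr$v, c(100, 0, 50))           # 6 slm = 100 mL/s
  expect_equal(tr$t, c(0, 0.1, 0.2))
  expect_identical(tr$channel, "flow")
})

test_that("slm -> mL/s -> slm round trips to machine precision", {
  x <- c(0.3, 6, 12.7, 60)
  expect_equal(x * (1000 / 60) * (60 / 1000), x, tolerance = 1e-15)
})

test_that("a file written by the fixture reads back identically", {
  tr <- square_flow(n_cycles = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace_csv(tr, path, "flow")
  rd <- read_flow_csv(path, units = "mL/s")
  expect_equal(rd$v, tr$v)
  expect_equal(rd$t, tr$t)
  # and tab-separated dialect autodetects
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_trace_csv(tr, path2, "flow", sep = "\t")
  rd2 <- read_flow_csv(path2, units = "mL/s")
  expect_equal(rd2$v, tr$v)
})

test_that("flow reader rejects malformed files", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time,volume", "0,1", "1,2"), path)
  expect_error(read_flow_csv(path), "column 'flow' not found")
  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time,flow", "0,1", "0,2", "1,3"), path2)
  expect_error(read_flow_csv(path2), "index 2")
  path3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(character(0), path3)
  expect_error(read_flow_csv(path3), "empty")
  expect_error(read_flow_csv(file.path(tempdir(), "nope.csv")), "not found")
})

test_that("pressure reader keeps declared units and guards absolute range", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time,pressure", "0,11.0", "0.1,11.0"), path)
  tr <- read_pressure_csv(path, units = "cmH2O_gauge")
  expect_equal(tr$v, c(11, 11))               # gauge passes through unchanged
  expect_identical(tr$units, "cmH2O")

  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time,pressure", "0,1013.25", "0.1,1013.25"), path2)
  tr2 <- read_pressure_csv(path2, units = "hPa_absolute")
  expect_identical(tr2$units, "hPa_absolute")
  bc <- baseline_correct(tr2, baseline = 1013.25)
  expect_equal(bc$v, c(0, 0))                 # baseline equals the samples

  path3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time,pressure", "0,250", "0.1,1000"), path3)
  expect_error(read_pressure_csv(path3, units = "hPa_absolute"),
               "plausible barometric range")
})

test_that("baseline correction is the exact hPa -> cmH2O affine map", {
  tt <- seq(0, 1, by = 0.01)
  tr <- waveform_trace(tt, rep(1000, length(tt)), "pressure",
                       units = "hPa_absolute")
  bc <- baseline_correct(tr, baseline_window = c(0, 1))
  expect_equal(bc$v, rep(0, length(tt)))
  tr2 <- waveform_trace(tt, c(rep(1000, 50), rep(1010, 51)), "pressure",
                        units = "hPa_absolute")
  bc2 <- baseline_correct(tr2, baseline = 1000)
  expect_equal(bc2$v[60], 10.1972)            # 10 hPa above baseline
  expect_identical(bc2$units, "cmH2O")
  # shifting the input by c shifts the output by exactly c * 1.01972
  tr3 <- waveform_trace(tt, tr2$v + 3.7, "pressure", units = "hPa_absolute")
  bc3 <- baseline_correct(tr3, baseline = 1000)
  expect_equal(bc3$v - bc2$v, rep(3.7 * 1.01972, length(tt)))
  expect_error(baseline_correct(tr, baseline_window = c(0.5, 0.5)),
               "positive-length")
  expect_error(baseline_correct(tr, baseline_window = c(5, 6)),
               "outside the trace")
})

test_that("resample_align interpolates onto a shared half-open grid", {
  t1 <- seq(0, 12, by = 0.02)
  t2 <- seq(1.5, 11.5, by = 0.013)
  tr1 <- waveform_trace(t1, sin(t1), "flow")
  tr2 <- waveform_trace(t2, cos(t2), "pressure", units = "cmH2O")
  al <- resample_align(list(tr1, tr2), rate = 100)
  expect_equal(al[[1]]$t, al[[2]]$t)
  expect_equal(al[[1]]$t[1], 1.5)
  expect_lt(max(al[[1]]$t), 11.5)             # no extrapolation at the end
  expect_equal(length(al[[1]]$t), 1000, tolerance = 0.002)
  expect_false(anyNA(al[[1]]$v))
  expect_false(anyNA(al[[2]]$v))
})

test_that("resampling a trace at its own rate keeps knot values", {
  tr <- square_flow(n_cycles = 3)
  al <- resample_align(list(tr), rate = 100)[[1]]
  idx <- match(round(al$t, 10), round(tr$t, 10))
  expect_equal(al$v, tr$v[idx])
})

test_that("resample_align is idempotent on aligned traces", {
  tr1 <- square_flow(n_cycles = 3)
  tr2 <- const_trace(7, duration = max(tr1$t), rate = 100)
  al <- resample_align(list(tr1, tr2), rate = 100)
  al2 <- resample_align(al, rate = 100)
  expect_lt(max(abs(al2[[1]]$v - al[[1]]$v[seq_along(al2[[1]]$v)])), 1e-9)
  expect_lt(max(abs(al2[[2]]$v - al[[2]]$v[seq_along(al2[[2]]$v)])), 1e-9)
})

test_that("disjoint or sub-second overlaps are alignment errors", {
  tr1 <- waveform_trace(seq(0, 5, 0.01), rep(1, 501), "flow")
  tr2 <- waveform_trace(seq(10, 15, 0.01), rep(1, 501), "flow")
  expect_error(resample_align(list(tr1, tr2)), "alignment error")
  tr3 <- waveform_trace(seq(4.8, 9, 0.01), rep(1, 421), "flow")
  expect_error(resample_align(list(tr1, tr3)), "alignment error")
})

test_that("result CSVs round-trip floats at 9 significant digits", {
  df <- data.frame(a = c(1 / 3, 2 / 7), b = c("x", "y"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_result_csv(df, path)
  rd <- utils::read.csv(path)
  expect_equal(rd$a, df$a, tolerance = 1e-8)
})
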