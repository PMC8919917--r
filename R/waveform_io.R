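#' Construct a waveform trace
#'
#' A `waveform_trace` is the package's basic container for one recorded
#' channel: a strictly increasing time base in seconds paired with sample
#' values, plus the channel kind, its units and a free-text source label.
#' After ingestion through [read_flow_csv()] / [read_pressure_csv()] and
#' [baseline_correct()], flow is always in mL/s and pressure in cmH2O gauge
#' (atmospheric-referenced), so downstream code never carries unit state.
#'
#' @param t Numeric vector of sample times in seconds, strictly increasing.
#' @param v Numeric vector of sample values, same length as `t` (length >= 2).
#' @param channel `"flow"` or `"pressure"`.
#' @param units Unit string. Canonical analysis units are `"mL/s"` for flow
#'   and `"cmH2O"` (gauge) for pressure; `"hPa_absolute"` marks a raw
#'   barometric pressure trace not yet referenced to atmosphere.
#' @param source_label Free text describing the sensor position, e.g.
#'   `"inspiratory-limb"`, `"expiratory-limb"`, `"common"`.
#' @param nominal_rate Nominal sampling rate in Hz, or `NA` if unknown.
#' @return An object of class `waveform_trace`.
#' @export
waveform_trace <- function(t, v, channel = c("flow", "pressure"),
                           units = NULL, source_label = "",
                           nominal_rate = NA_real_) {
  channel <- match.arg(channel)
  t <- as.numeric(t)
  v <- as.numeric(v)
  if (length(t) != length(v)) {
    stop("data error: time and value vectors differ in length (",
         length(t), " vs ", length(v), ")")
  }
  if (length(t) < 2L) {
    stop("data error: a waveform trace needs at least 2 samples")
  }
  if (anyNA(t) || anyNA(v)) {
    stop("data error: NA values in trace")
  }
  bad <- which(diff(t) <= 0)
  if (length(bad) > 0L) {
    stop("data error: timestamps not strictly increasing, first offending index ",
         bad[1L] + 1L)
  }
  if (is.null(units)) {
    units <- if (channel == "flow") "mL/s" else "cmH2O"
  }
  structure(
    list(t = t, v = v, channel = channel, units = units,
         source_label = source_label, nominal_rate = nominal_rate),
    class = "waveform_trace"
  )
}

#' @export
print.waveform_trace <- function(x, ...) {
  cat(sprintf("<waveform_trace> %s [%s] %s\n", x$channel, x$units,
              if (nzchar(x$source_label)) paste0("(", x$source_label, ")") else ""))
  cat(sprintf("  %d samples, t = %.3f .. %.3f s", length(x$t),
              x$t[1L], x$t[length(x$t)]))
  if (is.finite(x$nominal_rate)) cat(sprintf(", nominal %g Hz", x$nominal_rate))
  cat("\n")
  invisible(x)
}

#' @export
length.waveform_trace <- function(x) length(x$t)

trace_duration <- function(trace) trace$t[length(trace$t)] - trace$t[1L]

# Median sampling interval; segmentation and the simulator need a uniform grid.
trace_dt <- function(trace) stats::median(diff(trace$t))

assert_uniform_grid <- function(trace, tol = 1e-6) {
  dt <- diff(trace$t)
  if (max(dt) - min(dt) > tol * stats::median(dt)) {
    stop("argument error: trace is not on a uniform time grid")
  }
  invisible(trace)
}

read_delim_auto <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("format error: file not found: ", path)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) stop("data error: empty file: ", path)
  if (is.null(sep)) sep <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) == 0L) stop("data error: no data rows in ", path)
  df
}

get_column <- function(df, name, path) {
  if (!name %in% names(df)) {
    stop("format error: column '", name, "' not found in ", path,
         " (columns: ", paste(names(df), collapse = ", "), ")")
  }
  x <- suppressWarnings(as.numeric(df[[name]]))
  if (anyNA(x)) {
    stop("format error: column '", name, "' in ", path,
         " contains unparseable values (first at row ", which(is.na(x))[1L], ")")
  }
  x
}

time_to_seconds <- function(tt, time_units) {
  switch(time_units,
         s  = tt,
         ms = tt / 1000,
         us = tt / 1e6,
         stop("format error: unknown time units '", time_units, "'"))
}

#' Read a flow waveform from delimited text
#'
#' Reads one time column and one flow column from a comma- or tab-separated
#' file with a single header line, and converts to the canonical analysis
#' units (mL/s; 1 slm = 1 L/min = 1000/60 mL/s). Timestamps are re-expressed
#' as seconds from the first sample.
#'
#' @param path Path to the delimited text file.
#' @param time_col,flow_col Column names holding time and flow.
#' @param units Flow units as recorded: `"slm"` (standard liters per minute),
#'   `"L/min"`, or `"mL/s"`.
#' @param time_units Time units as recorded: `"s"`, `"ms"` or `"us"`.
#' @param sep Field separator; `NULL` (default) autodetects tab vs comma.
#' @param source_label Sensor position label, default `"common"` (proximal
#'   flow sensor on the common line).
#' @return A flow [waveform_trace()] in mL/s.
#' @export
read_flow_csv <- function(path, time_col = "time", flow_col = "flow",
                          units = c("slm", "L/min", "mL/s"),
                          time_units = "s", sep = NULL,
                          source_label = "common") {
  units <- match.arg(units)
  df <- read_delim_auto(path, sep)
  tt <- time_to_seconds(get_column(df, time_col, path), time_units)
  vv <- get_column(df, flow_col, path)
  scale <- switch(units, slm = 1000 / 60, `L/min` = 1000 / 60, `mL/s` = 1)
  tt <- tt - tt[1L]
  rate <- if (length(tt) > 1L) 1 / stats::median(diff(tt)) else NA_real_
  waveform_trace(tt, vv * scale, channel = "flow", units = "mL/s",
                 source_label = source_label, nominal_rate = rate)
}

#' Read a pressure waveform from delimited text
#'
#' Reads one time column and one pressure column. Gauge recordings
#' (`"cmH2O_gauge"`) are returned unchanged; absolute barometric recordings
#' (`"hPa_absolute"`) are kept in hPa and flagged as such — referencing to
#' atmosphere and conversion to cmH2O gauge happens in [baseline_correct()].
#' Absolute readings outside the plausible barometric range (300--1200 hPa)
#' are rejected.
#'
#' @inheritParams read_flow_csv
#' @param pressure_col Column name holding pressure.
#' @param units `"hPa_absolute"` or `"cmH2O_gauge"`.
#' @return A pressure [waveform_trace()], units `"hPa_absolute"` or `"cmH2O"`.
#' @export
read_pressure_csv <- function(path, time_col = "time", pressure_col = "pressure",
                              units = c("hPa_absolute", "cmH2O_gauge"),
                              time_units = "s", sep = NULL,
                              source_label = "") {
  units <- match.arg(units)
  df <- read_delim_auto(path, sep)
  tt <- time_to_seconds(get_column(df, time_col, path), time_units)
  vv <- get_column(df, pressure_col, path)
  if (units == "hPa_absolute" && (any(vv < 300) || any(vv > 1200))) {
    stop("data error: absolute pressure outside plausible barometric range ",
         "(300..1200 hPa), first offending value ",
         vv[which(vv < 300 | vv > 1200)[1L]], " hPa")
  }
  tt <- tt - tt[1L]
  rate <- if (length(tt) > 1L) 1 / stats::median(diff(tt)) else NA_real_
  waveform_trace(tt, vv, channel = "pressure",
                 units = if (units == "hPa_absolute") "hPa_absolute" else "cmH2O",
                 source_label = source_label, nominal_rate = rate)
}

#' Convert hPa to cmH2O
#'
#' Exact linear conversion used throughout: 1 hPa = 1.01972 cmH2O.
#' @param x Pressure (difference) in hPa.
#' @return Pressure in cmH2O.
#' @export
hpa_to_cmh2o <- function(x) x * 1.01972

#' Baseline-correct a pressure trace to cmH2O gauge
#'
#' Subtracts an atmospheric baseline from a pressure trace. The baseline is
#' either given explicitly or taken as the median of the samples inside
#' `baseline_window` (a `c(start, end)` interval in trace time, chosen over a
#' quiescent, circuit-open period). Absolute barometric traces (hPa) are
#' converted to cmH2O gauge via 1 hPa = 1.01972 cmH2O; traces already in
#' cmH2O are shifted only.
#'
#' @param trace A pressure [waveform_trace()].
#' @param baseline_window Numeric `c(start, end)` in seconds, within the trace.
#' @param baseline Explicit baseline value in the trace's raw units
#'   (overrides `baseline_window`).
#' @return A pressure [waveform_trace()] in cmH2O gauge.
#' @export
baseline_correct <- function(trace, baseline_window = NULL, baseline = NULL) {
  stopifnot(inherits(trace, "waveform_trace"))
  if (trace$channel != "pressure") {
    stop("argument error: baseline_correct applies to pressure traces")
  }
  if (is.null(baseline)) {
    if (is.null(baseline_window)) {
      stop("argument error: give either baseline_window or baseline")
    }
    if (length(baseline_window) != 2L || baseline_window[2L] <= baseline_window[1L]) {
      stop("argument error: baseline window must be a positive-length interval")
    }
    if (baseline_window[1L] < trace$t[1L] - 1e-9 ||
        baseline_window[2L] > trace$t[length(trace$t)] + 1e-9) {
      stop("argument error: baseline window lies outside the trace")
    }
    sel <- trace$t >= baseline_window[1L] & trace$t <= baseline_window[2L]
    if (!any(sel)) stop("argument error: baseline window contains no samples")
    baseline <- stats::median(trace$v[sel])
  }
  out <- trace$v - baseline
  if (identical(trace$units, "hPa_absolute")) out <- hpa_to_cmh2o(out)
  waveform_trace(trace$t, out, channel = "pressure", units = "cmH2O",
                 source_label = trace$source_label,
                 nominal_rate = trace$nominal_rate)
}

#' Resample traces onto a shared uniform grid
#'
#' Linearly interpolates every trace onto one uniform grid covering the
#' overlap of their time supports. The grid is half-open
#' `[t_start, t_end)`: points are `t_start + k/rate` for `k = 0, 1, ...`
#' strictly before the end of overlap, so no trace is ever extrapolated.
#' Traces are assumed to share a clock (each recording's `t` is comparable);
#' when recordings start simultaneously this is the per-file
#' seconds-from-first-sample produced by the readers.
#'
#' @param traces A list of [waveform_trace()] objects (or a single trace).
#' @param rate Target rate in Hz (> 0); default 100 Hz, above the nominal
#'   rate of both sensor families and ample for breath morphology at
#'   respiratory rates up to 120/min.
#' @return A list of traces on the identical grid, same order as the input.
#' @export
resample_align <- function(traces, rate = 100) {
  if (inherits(traces, "waveform_trace")) traces <- list(traces)
  stopifnot(length(traces) >= 1L, rate > 0)
  for (tr in traces) stopifnot(inherits(tr, "waveform_trace"))
  t0 <- max(vapply(traces, function(x) x$t[1L], 0))
  t1 <- min(vapply(traces, function(x) x$t[length(x$t)], 0))
  if (t1 - t0 < 1) {
    stop("alignment error: traces overlap for ", format(max(0, t1 - t0)),
         " s (< 1 s required)")
  }
  n <- floor((t1 - t0) * rate - 1e-9) + 1L
  grid <- t0 + (seq_len(n) - 1L) / rate
  lapply(traces, function(tr) {
    vi <- stats::approx(tr$t, tr$v, xout = grid, method = "linear",
                        rule = 1)$y
    waveform_trace(grid, vi, channel = tr$channel, units = tr$units,
                   source_label = tr$source_label, nominal_rate = rate)
  })
}

fmt9 <- function(x) {
  if (is.numeric(x)) sprintf("%.9g", x) else x
}

#' Write a table with full-precision floats
#'
#' CSV writer used for breath tables and window summaries; numeric columns
#' are written with 9 significant digits so re-reading reproduces the
#' analysis to float precision.
#'
#' @param df A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_result_csv <- function(df, path) {
  out <- as.data.frame(lapply(df, fmt9), stringsAsFactors = FALSE,
                       check.names = FALSE)
  names(out) <- names(df)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write run metadata as JSON
#'
#' Records every threshold, rate, seed and package version that shaped a run,
#' so results can be reproduced and detection conventions audited.
#'
#' @param meta A named list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_metadata <- function(meta, path) {
  meta$ventbench_version <- as.character(utils::packageVersion("ventbench"))
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
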