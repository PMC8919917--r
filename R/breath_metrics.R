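#' Ventilator settings
#'
#' Target settings of a pressure-controlled ventilation run, used to compute
#' delivery errors (dPIP = mean PIP - PIP_target, dPEEP = mean PEEP -
#' PEEP_target) and as simulator inputs. Defaults are the crossover protocol
#' settings: PIP 11 cmH2O, PEEP 3 cmH2O, rate 40 breaths/min, I:E 1:1.
#'
#' @param PIP_target Target peak inspiratory pressure, cmH2O.
#' @param PEEP_target Target positive end-expiratory pressure, cmH2O.
#' @param RR_target Target respiratory rate, breaths/min.
#' @param IE_set Set inspiratory:expiratory time ratio (dimensionless, > 0).
#' @return A `vent_settings` list.
#' @export
vent_settings <- function(PIP_target = 11, PEEP_target = 3,
                          RR_target = 40, IE_set = 1) {
  stopifnot(PEEP_target >= 0, PIP_target > PEEP_target,
            RR_target > 0, IE_set > 0)
  structure(list(PIP_target = PIP_target, PEEP_target = PEEP_target,
                 RR_target = RR_target, IE_set = IE_set),
            class = "vent_settings")
}

#' Default breath-detection thresholds
#'
#' Detection conventions for [segment_breaths()]. The source recordings'
#' own detection rule is not recoverable, so these are explicit, recorded in
#' run metadata, and configurable.
#'
#' @param theta_on Inspiration onset threshold on flow, mL/s. Default 5.
#' @param debounce Time flow must have been below `theta_on` before an onset
#'   counts, seconds. Default 0.05.
#' @param min_cycle Minimum total breath duration, seconds; shorter cycles
#'   are discarded. Default 0.2.
#' @return A named list of thresholds.
#' @export
segmentation_params <- function(theta_on = 5, debounce = 0.05, min_cycle = 0.2) {
  stopifnot(theta_on > 0, debounce >= 0, min_cycle >= 0)
  list(theta_on = theta_on, debounce = debounce, min_cycle = min_cycle)
}

#' Segment a flow waveform into respiratory cycles
#'
#' Inspiration starts when flow rises above `theta_on` after having been at
#' or below it for at least `debounce`; inspiration ends at the first
#' downward zero crossing after onset; expiration ends at the next
#' inspiration onset. The leading partial cycle (before the first onset) and
#' the trailing partial cycle (after the last onset) are discarded, as are
#' cycles shorter than `min_cycle` or with no inspiratory zero crossing.
#'
#' @param flow A flow [waveform_trace()] in mL/s on a uniform grid of at
#'   least 50 Hz.
#' @param params Thresholds from [segmentation_params()].
#' @return A data frame with one row per complete breath: `t_start`,
#'   `t_insp_end`, `t_end`, `T_insp`, `T_exp`, `IE`, `RR_inst`. Empty (zero
#'   rows) when flow never crosses the threshold.
#' @export
segment_breaths <- function(flow, params = segmentation_params()) {
  stopifnot(inherits(flow, "waveform_trace"))
  if (flow$channel != "flow") {
    stop("argument error: segment_breaths expects a flow trace")
  }
  assert_uniform_grid(flow)
  dt <- trace_dt(flow)
  if (1 / dt < 50 - 1e-6) {
    stop("argument error: flow must be sampled at >= 50 Hz (got ",
         format(1 / dt), " Hz)")
  }
  t <- flow$t
  v <- flow$v
  n <- length(v)
  above <- v > params$theta_on

  empty <- data.frame(t_start = numeric(0), t_insp_end = numeric(0),
                      t_end = numeric(0), T_insp = numeric(0),
                      T_exp = numeric(0), IE = numeric(0),
                      RR_inst = numeric(0))
  if (!any(above)) return(empty)

  rises <- which(above & !c(TRUE, above[-n]))  # below -> above transitions
  # a trace that starts above threshold is mid-inspiration: not an onset
  last_above <- cummax(ifelse(above, seq_len(n), 0L))  # last above-index so far
  onsets <- vapply(rises, function(i) {
    j <- last_above[i - 1L]
    gap <- if (j > 0L) t[i] - t[j] else Inf
    gap >= params$debounce - 1e-9
  }, TRUE)
  onsets <- rises[onsets]
  if (length(onsets) < 2L) return(empty)

  recs <- vector("list", length(onsets) - 1L)
  for (k in seq_len(length(onsets) - 1L)) {
    i0 <- onsets[k]
    i2 <- onsets[k + 1L]
    neg <- which(v[(i0 + 1L):(i2 - 1L)] < 0)
    if (length(neg) == 0L) next
    i1 <- i0 + neg[1L]
    total <- t[i2] - t[i0]
    if (total < params$min_cycle) next
    T_insp <- t[i1] - t[i0]
    T_exp <- t[i2] - t[i1]
    recs[[k]] <- data.frame(t_start = t[i0], t_insp_end = t[i1], t_end = t[i2],
                            T_insp = T_insp, T_exp = T_exp,
                            IE = T_insp / T_exp,
                            RR_inst = 60 / (T_insp + T_exp))
  }
  recs <- recs[!vapply(recs, is.null, TRUE)]
  if (length(recs) == 0L) return(empty)
  do.call(rbind, recs)
}

trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((x[-1L] - x[-n]) * (y[-1L] + y[-n])) / 2
}

#' Tidal volume of one breath
#'
#' Area under the flow waveform during inspiration (`[t_start, t_insp_end)`),
#' by trapezoidal integration over the samples in the window, clipped below
#' at zero. Flow in mL/s and time in s give volume in mL.
#'
#' @param flow A flow [waveform_trace()] in mL/s.
#' @param t_start,t_insp_end Inspiration boundaries, seconds, inside the
#'   trace support.
#' @return Tidal volume in mL.
#' @export
tidal_volume <- function(flow, t_start, t_insp_end) {
  stopifnot(inherits(flow, "waveform_trace"))
  if (t_start < flow$t[1L] - 1e-9 ||
      t_insp_end > flow$t[length(flow$t)] + 1e-9 || t_insp_end <= t_start) {
    stop("argument error: breath boundaries outside trace support")
  }
  # samples in [t_start, t_insp_end); the interval is closed on the right by
  # flat extension of the last inspiratory sample, so the expiratory spike at
  # the sample marking the zero crossing never leaks into the integral
  inner <- flow$t > t_start + 1e-12 & flow$t < t_insp_end - 1e-12
  v0 <- stats::approx(flow$t, flow$v, t_start, rule = 2)$y
  xs <- c(t_start, flow$t[inner])
  ys <- c(v0, flow$v[inner])
  xs <- c(xs, t_insp_end)
  ys <- c(ys, ys[length(ys)])
  max(0, trapz(xs, ys))
}

#' Peak inspiratory and end-expiratory pressure of one breath
#'
#' PIP is the maximum pressure over the whole cycle `[t_start, t_end)`.
#' PEEP is the mean pressure over the final 10% of the expiratory phase
#' (at least 3 samples) — a mean rather than the cycle minimum, so sensor
#' noise does not bias PEEP downward.
#'
#' @param pressure A pressure [waveform_trace()] (cmH2O gauge) time-aligned
#'   with the flow used for segmentation.
#' @param t_start,t_insp_end,t_end Breath boundaries in seconds.
#' @return Named numeric `c(PIP =, PEEP =)` in cmH2O.
#' @export
pip_peep <- function(pressure, t_start, t_insp_end, t_end) {
  stopifnot(inherits(pressure, "waveform_trace"))
  sel <- pressure$t >= t_start - 1e-9 & pressure$t < t_end - 1e-9
  if (sum(sel) < 3L) {
    stop("data error: breath window contains fewer than 3 pressure samples")
  }
  pip <- max(pressure$v[sel])
  T_exp <- t_end - t_insp_end
  tail_start <- t_end - 0.1 * T_exp
  tsel <- pressure$t >= tail_start - 1e-9 & pressure$t < t_end - 1e-9
  if (sum(tsel) < 3L) {
    idx <- which(sel)
    tsel <- idx[seq.int(max(1L, length(idx) - 2L), length(idx))]
  } else {
    tsel <- which(tsel)
  }
  peep <- mean(pressure$v[tsel])
  c(PIP = pip, PEEP = peep)
}

#' Segment flow and derive the full per-breath table
#'
#' Convenience wrapper: runs [segment_breaths()], then [tidal_volume()] per
#' breath and, when a pressure trace is given, [pip_peep()] per breath.
#'
#' @param flow A flow [waveform_trace()] in mL/s on a uniform grid.
#' @param pressure Optional aligned pressure [waveform_trace()] (cmH2O).
#' @param params Thresholds from [segmentation_params()].
#' @return A breath table data frame: segmentation columns plus `V_T` (mL)
#'   and, with pressure, `PIP` and `PEEP` (cmH2O).
#' @export
analyze_breaths <- function(flow, pressure = NULL,
                            params = segmentation_params()) {
  br <- segment_breaths(flow, params)
  if (nrow(br) == 0L) {
    br$V_T <- numeric(0)
    if (!is.null(pressure)) { br$PIP <- numeric(0); br$PEEP <- numeric(0) }
    return(br)
  }
  br$V_T <- vapply(seq_len(nrow(br)), function(i) {
    tidal_volume(flow, br$t_start[i], br$t_insp_end[i])
  }, 0)
  if (!is.null(pressure)) {
    pp <- vapply(seq_len(nrow(br)), function(i) {
      pip_peep(pressure, br$t_start[i], br$t_insp_end[i], br$t_end[i])
    }, c(PIP = 0, PEEP = 0))
    br$PIP <- pp["PIP", ]
    br$PEEP <- pp["PEEP", ]
  }
  br
}

#' Protocol sampling windows
#'
#' The crossover protocol samples a 1-min stretch of waveform at the start of
#' ventilation and every 10 min thereafter. This returns every window of
#' `width` starting at `offset + k*step` whose full width fits inside the
#' trace.
#'
#' @param trace_duration Total trace duration in seconds.
#' @param offset First window start, seconds (default 0).
#' @param step Window spacing, seconds (default 600 = 10 min).
#' @param width Window width, seconds (default 60 = 1 min).
#' @return Data frame with columns `start` and `duration` (seconds).
#' @export
protocol_windows <- function(trace_duration, offset = 0, step = 600, width = 60) {
  stopifnot(step > 0, width > 0)
  if (trace_duration < width) {
    stop("argument error: trace shorter (", trace_duration,
         " s) than the window width (", width, " s)")
  }
  starts <- seq(offset, trace_duration - width, by = step)
  data.frame(start = starts, duration = width)
}

#' Summarize breaths within one protocol window
#'
#' Arithmetic means of the per-breath metrics over the breaths lying fully
#' inside the window (breaths straddling an edge belong to no window), plus
#' the delivery errors dPIP = mean PIP - PIP_target and dPEEP = mean PEEP -
#' PEEP_target, and minute ventilation = (sum of V_T in the window / window
#' duration in minutes) / body mass.
#'
#' @param breaths A breath table from [analyze_breaths()].
#' @param settings A [vent_settings()].
#' @param mass Body mass in kg (for mL/kg scaling); `NA` to skip.
#' @param window_start,window_duration Window location, seconds.
#' @return A one-row data frame (`WindowSummary`); when the window holds no
#'   complete breath, a row with `n_breaths = 0`, all metrics `NA` and
#'   `empty = TRUE`, which downstream averaging excludes.
#' @export
summarize_window <- function(breaths, settings, mass,
                             window_start, window_duration) {
  stopifnot(inherits(settings, "vent_settings"))
  w0 <- window_start
  w1 <- window_start + window_duration
  inw <- breaths$t_start >= w0 - 1e-9 & breaths$t_end <= w1 + 1e-9
  b <- breaths[inw, , drop = FALSE]
  has_p <- all(c("PIP", "PEEP") %in% names(b))
  if (nrow(b) == 0L) {
    return(data.frame(window_start = w0 / 60, n_breaths = 0L,
                      mean_V_T = NA_real_, mean_V_T_per_kg = NA_real_,
                      mean_RR = NA_real_, mean_IE = NA_real_,
                      mean_PIP = NA_real_, mean_PEEP = NA_real_,
                      dPIP = NA_real_, dPEEP = NA_real_,
                      minute_ventilation = NA_real_, empty = TRUE))
  }
  mean_pip <- if (has_p) mean(b$PIP) else NA_real_
  mean_peep <- if (has_p) mean(b$PEEP) else NA_real_
  mv <- (sum(b$V_T) / (window_duration / 60))
  data.frame(
    window_start = w0 / 60,
    n_breaths = nrow(b),
    mean_V_T = mean(b$V_T),
    mean_V_T_per_kg = if (is.finite(mass)) mean(b$V_T) / mass else NA_real_,
    mean_RR = mean(b$RR_inst),
    mean_IE = mean(b$IE),
    mean_PIP = mean_pip,
    mean_PEEP = mean_peep,
    dPIP = mean_pip - settings$PIP_target,
    dPEEP = mean_peep - settings$PEEP_target,
    minute_ventilation = if (is.finite(mass)) mv / mass else NA_real_,
    empty = FALSE
  )
}

#' Window summaries over a whole recording
#'
#' Applies [summarize_window()] at every [protocol_windows()] position.
#'
#' @inheritParams summarize_window
#' @param trace_duration Recording duration in seconds.
#' @param offset,step,width Window schedule, seconds (see
#'   [protocol_windows()]).
#' @return A data frame with one row per window.
#' @export
summarize_protocol <- function(breaths, settings, mass, trace_duration,
                               offset = 0, step = 600, width = 60) {
  win <- protocol_windows(trace_duration, offset, step, width)
  do.call(rbind, lapply(seq_len(nrow(win)), function(i) {
    summarize_window(breaths, settings, mass, win$start[i], win$duration[i])
  }))
}
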