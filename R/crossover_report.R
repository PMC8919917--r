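#' Analyze one ventilation recording end-to-end
#'
#' The per-recording pipeline: time-align flow and pressure onto one uniform
#' grid, segment breaths from flow, reconstruct airway pressure (fusing
#' dual-limb recordings through the flow-derived phases when both limbs are
#' given), derive the per-breath table, summarize the protocol windows, and
#' compute Poincare SD1/SD2 of the per-breath PIP and PEEP series. Poincare
#' lag-1 pairs are formed only within a protocol window, never across the
#' gap between windows.
#'
#' @param flow Flow [waveform_trace()] in mL/s.
#' @param pressure Single airway-pressure trace (cmH2O gauge), for circuits
#'   with one sensor; or `NULL`.
#' @param pressure_insp,pressure_exp Dual-limb pressure traces (cmH2O
#'   gauge), for circuits whose limbs are isolated by a three-way valve; or
#'   `NULL`.
#' @param settings A [vent_settings()].
#' @param mass Body mass, kg (`NA` skips per-kg scaling).
#' @param rate Analysis grid rate, Hz.
#' @param seg Thresholds from [segmentation_params()].
#' @param window_offset,window_step,window_width Protocol window schedule,
#'   seconds; defaults 0/600/60 (a 1-min sample at the start and every
#'   10 min).
#' @return A list: `breaths` (per-breath table), `windows` (per-window
#'   summaries), `poincare` (results for PIP and PEEP, or `NULL` without
#'   pressure), `pressure` (the aligned, fused airway-pressure trace),
#'   `summary` (one-row data frame of per-recording means over non-empty
#'   windows plus the Poincare statistics).
#' @export
analyze_recording <- function(flow, pressure = NULL,
                              pressure_insp = NULL, pressure_exp = NULL,
                              settings = vent_settings(), mass = NA_real_,
                              rate = 100, seg = segmentation_params(),
                              window_offset = 0, window_step = 600,
                              window_width = 60) {
  traces <- list(flow = flow)
  if (!is.null(pressure_insp) || !is.null(pressure_exp)) {
    if (is.null(pressure_insp) || is.null(pressure_exp)) {
      stop("argument error: dual-limb fusion needs both pressure_insp and ",
           "pressure_exp")
    }
    traces$insp <- pressure_insp
    traces$exp <- pressure_exp
  } else if (!is.null(pressure)) {
    traces$pressure <- pressure
  }
  al <- resample_align(traces, rate = rate)
  names(al) <- names(traces)
  flow_al <- al$flow

  br0 <- segment_breaths(flow_al, seg)
  p_al <- NULL
  if (!is.null(al$insp)) {
    phases <- if (nrow(br0) > 0L) phases_from_breaths(br0) else NULL
    p_al <- fuse_pressures(al$insp, al$exp, phases)
  } else if (!is.null(al$pressure)) {
    p_al <- al$pressure
  }
  breaths <- analyze_breaths(flow_al, p_al, seg)

  dur <- trace_duration(flow_al)
  # recordings shorter than one protocol window get a single window
  # spanning what is there
  window_width <- min(window_width, dur)
  windows <- summarize_protocol(breaths, settings, mass, dur,
                                offset = window_offset, step = window_step,
                                width = window_width)

  # window membership for Poincare segment gating
  poin <- NULL
  win_id <- rep(NA_integer_, nrow(breaths))
  if (nrow(breaths) > 0L) {
    win <- protocol_windows(dur, window_offset, window_step, window_width)
    for (i in seq_len(nrow(win))) {
      inw <- breaths$t_start >= win$start[i] - 1e-9 &
        breaths$t_end <= win$start[i] + win$duration[i] + 1e-9
      win_id[inw] <- i
    }
  }
  if (!is.null(p_al) && sum(!is.na(win_id)) >= 3L) {
    sel <- !is.na(win_id)
    poin <- list(
      PIP = poincare_sd(breaths$PIP[sel], label = "PIP",
                        segments = win_id[sel]),
      PEEP = poincare_sd(breaths$PEEP[sel], label = "PEEP",
                         segments = win_id[sel])
    )
  }

  ok <- !windows$empty
  wmean <- function(col) if (any(ok)) mean(windows[[col]][ok]) else NA_real_
  summary <- data.frame(
    n_breaths = nrow(breaths),
    n_windows = sum(ok),
    V_T = wmean("mean_V_T"),
    V_T_per_kg = wmean("mean_V_T_per_kg"),
    RR = wmean("mean_RR"),
    IE = wmean("mean_IE"),
    PIP = wmean("mean_PIP"),
    PEEP = wmean("mean_PEEP"),
    dPIP = wmean("dPIP"),
    dPEEP = wmean("dPEEP"),
    minute_ventilation = wmean("minute_ventilation"),
    SD1_PIP = if (!is.null(poin)) poin$PIP$sd1 else NA_real_,
    SD2_PIP = if (!is.null(poin)) poin$PIP$sd2 else NA_real_,
    SD1_PEEP = if (!is.null(poin)) poin$PEEP$sd1 else NA_real_,
    SD2_PEEP = if (!is.null(poin)) poin$PEEP$sd2 else NA_real_
  )
  list(breaths = breaths, windows = windows, poincare = poin,
       pressure = p_al, summary = summary)
}

read_recording_traces <- function(rec) {
  defaults <- list(time_col = "time", flow_col = "flow",
                   pressure_col = "pressure", flow_units = "mL/s",
                   pressure_units = "cmH2O_gauge", time_units = "s")
  for (nm in names(defaults)) if (is.null(rec[[nm]])) rec[[nm]] <- defaults[[nm]]
  out <- list()
  out$flow <- read_flow_csv(rec$flow, rec$time_col, rec$flow_col,
                            units = rec$flow_units,
                            time_units = rec$time_units)
  rp <- function(path, label) {
    tr <- read_pressure_csv(path, rec$time_col, rec$pressure_col,
                            units = rec$pressure_units,
                            time_units = rec$time_units,
                            source_label = label)
    if (identical(tr$units, "hPa_absolute")) {
      if (!is.null(rec$baseline)) {
        tr <- baseline_correct(tr, baseline = rec$baseline)
      } else if (!is.null(rec$baseline_window)) {
        tr <- baseline_correct(tr, baseline_window = unlist(rec$baseline_window))
      } else {
        stop("config error: absolute pressure recording ", path,
             " needs 'baseline' or 'baseline_window'")
      }
    }
    tr
  }
  if (!is.null(rec$pressure_insp)) {
    out$pressure_insp <- rp(rec$pressure_insp, "inspiratory-limb")
    out$pressure_exp <- rp(rec$pressure_exp, "expiratory-limb")
  } else if (!is.null(rec$pressure)) {
    out$pressure <- rp(rec$pressure, "common")
  }
  out
}

recording_paths <- function(rec) {
  unlist(rec[intersect(names(rec),
                       c("flow", "pressure", "pressure_insp", "pressure_exp"))])
}

#' Run the full two-ventilator crossover analysis
#'
#' Orchestrates the whole crossover workflow from a single config: for every
#' subject and both ventilators, reads the recordings, runs
#' [analyze_recording()], and writes the per-breath table and window
#' summaries; across subjects it builds the group comparison table — one row
#' per metric (V_T/kg, dPIP, dPEEP, RR, I:E, minute ventilation, SD1/SD2 of
#' PIP and PEEP) with group means and SDs, the Shapiro-Wilk gate p, the test
#' used and its p-value via [paired_compare()] — plus a provenance JSON
#' recording every threshold and option. Every referenced file is checked
#' before any computation starts; a failure in a later stage keeps the
#' outputs written so far and records the failure in `error_manifest.json`.
#'
#' @param config A named list, or path to a YAML/JSON file, with entries:
#'   \describe{
#'     \item{subjects}{list; each element has `id`, `mass` (kg) and
#'       `recordings`, a named list with one entry per ventilator label;
#'       each entry gives `flow` and either `pressure` or `pressure_insp` +
#'       `pressure_exp` (file paths), with optional `flow_units`
#'       (default mL/s), `pressure_units` (default cmH2O_gauge; for
#'       hPa_absolute also `baseline` or `baseline_window`), `time_col`,
#'       `flow_col`, `pressure_col`, `time_units`.}
#'     \item{settings}{named list per ventilator label (or a single list for
#'       both) of [vent_settings()] arguments.}
#'     \item{options}{optional: `rate`, `theta_on`, `debounce`, `min_cycle`,
#'       `window_offset`, `window_step`, `window_width`, `alpha`.}
#'     \item{output_dir}{directory for all outputs.}
#'   }
#' @return Invisibly, a list: `per_subject` (nested analysis results),
#'   `subject_summaries` (one row per subject x ventilator), `comparison`
#'   (the group table), `errors` (per-stage failures, empty on success),
#'   `output_dir`.
#' @export
run_crossover_report <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config, ignore.case = TRUE)) {
      jsonlite::read_json(config, simplifyVector = FALSE)
    } else {
      yaml::read_yaml(config)
    }
  }
  if (is.null(config$subjects) || length(config$subjects) == 0L) {
    stop("config error: no subjects")
  }
  if (is.null(config$output_dir)) stop("config error: no output_dir")

  # full config validation before any computation
  vent_labels <- NULL
  for (s in config$subjects) {
    if (is.null(s$id) || is.null(s$recordings)) {
      stop("config error: every subject needs an id and recordings")
    }
    labs <- sort(names(s$recordings))
    if (is.null(vent_labels)) vent_labels <- labs
    if (!identical(labs, vent_labels)) {
      stop("config error: subject ", s$id,
           " has ventilator labels differing from the first subject")
    }
    for (lab in labs) {
      paths <- recording_paths(s$recordings[[lab]])
      missing <- paths[!file.exists(paths)]
      if (length(missing) > 0L) {
        stop("config error: file not found for subject ", s$id, " / ", lab,
             ": ", paste(missing, collapse = ", "))
      }
    }
  }
  if (length(vent_labels) != 2L) {
    stop("config error: crossover comparison needs exactly 2 ventilator ",
         "labels per subject (got ", length(vent_labels), ")")
  }

  opt <- config$options
  getopt <- function(nm, default) if (is.null(opt[[nm]])) default else opt[[nm]]
  rate <- getopt("rate", 100)
  seg <- segmentation_params(getopt("theta_on", 5), getopt("debounce", 0.05),
                             getopt("min_cycle", 0.2))
  w_off <- getopt("window_offset", 0)
  w_step <- getopt("window_step", 600)
  w_width <- getopt("window_width", 60)
  alpha <- getopt("alpha", 0.05)

  settings_for <- function(lab) {
    sc <- config$settings
    if (!is.null(sc[[lab]])) sc <- sc[[lab]]
    do.call(vent_settings, sc[intersect(names(sc),
      c("PIP_target", "PEEP_target", "RR_target", "IE_set"))])
  }

  outdir <- config$output_dir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  errors <- list()
  per_subject <- list()
  rows <- list()

  for (s in config$subjects) {
    per_subject[[s$id]] <- list()
    for (lab in vent_labels) {
      stage <- paste0(s$id, "/", lab)
      res <- tryCatch({
        tr <- read_recording_traces(s$recordings[[lab]])
        a <- analyze_recording(
          flow = tr$flow, pressure = tr$pressure,
          pressure_insp = tr$pressure_insp, pressure_exp = tr$pressure_exp,
          settings = settings_for(lab),
          mass = if (is.null(s$mass)) NA_real_ else s$mass,
          rate = rate, seg = seg, window_offset = w_off,
          window_step = w_step, window_width = w_width)
        write_result_csv(a$breaths,
                         file.path(outdir, paste0(s$id, "_", lab, "_breaths.csv")))
        write_result_csv(a$windows,
                         file.path(outdir, paste0(s$id, "_", lab, "_windows.csv")))
        a
      }, error = function(e) e)
      if (inherits(res, "error")) {
        errors[[stage]] <- conditionMessage(res)
      } else {
        per_subject[[s$id]][[lab]] <- res
        rows[[stage]] <- cbind(data.frame(subject = s$id, ventilator = lab),
                               res$summary)
      }
    }
  }

  subject_summaries <- if (length(rows)) do.call(rbind, rows) else NULL
  comparison <- NULL
  if (!is.null(subject_summaries) && length(errors) == 0L) {
    metrics <- c("V_T_per_kg", "dPIP", "dPEEP", "RR", "IE",
                 "minute_ventilation", "SD1_PIP", "SD2_PIP",
                 "SD1_PEEP", "SD2_PEEP")
    l1 <- vent_labels[1L]; l2 <- vent_labels[2L]
    cmp_rows <- lapply(metrics, function(m) {
      x1 <- subject_summaries[subject_summaries$ventilator == l1, m]
      x2 <- subject_summaries[subject_summaries$ventilator == l2, m]
      if (any(!is.finite(x1)) || any(!is.finite(x2))) return(NULL)
      pc <- withCallingHandlers(
        paired_compare(x1, x2, alpha = alpha),
        warning = function(w) invokeRestart("muffleWarning"))
      df <- data.frame(metric = m,
                       mean_1 = mean(x1), sd_1 = stats::sd(x1),
                       mean_2 = mean(x2), sd_2 = stats::sd(x2),
                       n = pc$n, normality_p = pc$normality_p,
                       test_used = pc$test_used, statistic = pc$statistic,
                       p_value = pc$p_value, degenerate = pc$degenerate)
      names(df)[2:5] <- c(paste0("mean_", l1), paste0("sd_", l1),
                          paste0("mean_", l2), paste0("sd_", l2))
      df
    })
    cmp_rows <- cmp_rows[!vapply(cmp_rows, is.null, TRUE)]
    if (length(cmp_rows)) {
      comparison <- do.call(rbind, cmp_rows)
      write_result_csv(comparison, file.path(outdir, "comparison.csv"))
      write_result_csv(subject_summaries,
                       file.path(outdir, "subject_summaries.csv"))
    }
  }

  write_run_metadata(
    list(rate = rate, segmentation = seg,
         windows = list(offset = w_off, step = w_step, width = w_width),
         alpha = alpha, ventilators = as.list(vent_labels),
         n_subjects = length(config$subjects),
         poincare = list(sd = "sample", pairs = "within-window only"),
         errors = errors),
    file.path(outdir, "provenance.json"))
  if (length(errors) > 0L) {
    jsonlite::write_json(errors, file.path(outdir, "error_manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    warning("stage failures recorded in error_manifest.json: ",
            paste(names(errors), collapse = ", "))
  }
  invisible(list(per_subject = per_subject,
                 subject_summaries = subject_summaries,
                 comparison = comparison, errors = errors,
                 output_dir = outdir))
}
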