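# Fixtures built in code: small waveforms with known structure.

# square flow wave: +amp for t_on, -amp for t_off, n_cycles times,
# padded with lead/trail seconds of zero flow, on a uniform grid
square_flow <- function(n_cycles = 21, amp = 100, t_on = 0.75, t_off = 0.75,
                        rate = 100, lead = 1, trail = 1) {
  dt <- 1 / rate
  cyc <- c(rep(amp, round(t_on * rate)), rep(-amp, round(t_off * rate)))
  v <- c(rep(0, round(lead * rate)), rep(cyc, n_cycles),
         rep(0, round(trail * rate)))
  waveform_trace((seq_along(v) - 1L) * dt, v, channel = "flow",
                 units = "mL/s", nominal_rate = rate)
}

# constant-valued trace
const_trace <- function(value, duration = 10, rate = 100,
                        channel = "pressure", units = "cmH2O") {
  tt <- seq(0, duration, by = 1 / rate)
  waveform_trace(tt, rep(value, length(tt)), channel = channel,
                 units = units, nominal_rate = rate)
}

write_trace_csv <- function(trace, path, value_name = "flow", sep = ",") {
  df <- data.frame(time = trace$t, v = trace$v)
  names(df)[2] <- value_name
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  path
}

quiet_sim <- function(mode, ...) {
  vent_source_params(mode, jitter_sd = 0, noise_sd_flow = 0,
                     noise_sd_pressure = 0, ...)
}
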