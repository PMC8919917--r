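#' Single-compartment lung parameters
#'
#' Linear one-compartment respiratory mechanics: alveolar pressure is
#' `P_alv = (V - V_rest)/C` and airway flow obeys `dV/dt = (P_aw - P_alv)/R`.
#' Defaults approximate an intubated small-animal (rabbit-sized) respiratory
#' system: compliance 2 mL/cmH2O and resistance 0.1 cmH2O.s/mL — the narrow
#' (3 mm) endotracheal tube dominates resistance — giving a time constant
#' RC = 0.2 s, so inspiratory flow decelerates over, but persists through, a
#' 0.75 s inspiration.
#'
#' @param C Compliance, mL/cmH2O (> 0).
#' @param R Airway resistance, cmH2O.s/mL (> 0).
#' @param V_rest Resting volume offset, mL.
#' @return A `lung_params` list.
#' @export
lung_params <- function(C = 2, R = 0.1, V_rest = 0) {
  stopifnot(C > 0, R > 0)
  structure(list(C = C, R = R, V_rest = V_rest), class = "lung_params")
}

#' Ventilator pressure-source parameters
#'
#' Two source models drive the simulated circuit:
#' * `"square"` — a regulator-driven ICU-style source that steps between the
#'   set pressures almost instantaneously (small time constants, default
#'   0.02 s) and actively holds PEEP during expiration (`exp_floor =
#'   PEEP_set`).
#' * `"turbine"` — a blower whose finite spin-up/spin-down makes pressure
#'   transitions first-order with time constants `tau_up`/`tau_down`
#'   (default 0.25 s). During expiration the turbine is braked and its
#'   pressure collapses toward atmosphere (`exp_floor = 0`); PEEP is then
#'   held by the PEEP valve, not the source. The spin-up from near-zero
#'   delays the onset of inspiratory flow, which is what shortens the
#'   measured I:E ratio relative to the set ratio.
#'
#' Breath-to-breath variability of the delivered peak pressure is a
#' stationary AR(1) offset added to `PIP_set` (see [pip_jitter_series()]).
#' The jitter defaults are anchored to the Poincare variability each source
#' type shows in practice: turbine `phi = 0.69`, innovation SD 0.40 cmH2O
#' (implying SD1 ~ 0.31, SD2 ~ 0.72 cmH2O); square `phi = 0.93`, innovation
#' SD 0.072 cmH2O (implying SD1 ~ 0.052, SD2 ~ 0.27 cmH2O).
#'
#' @param mode `"square"` or `"turbine"`.
#' @param PIP_set,PEEP_set Set pressures, cmH2O (`PIP_set >= PEEP_set`).
#' @param RR_set Set respiratory rate, breaths/min.
#' @param IE_set Set I:E ratio; the set inspiratory time is
#'   `IE_set/(1+IE_set) * 60/RR_set`.
#' @param tau_up,tau_down Source rise/fall time constants, s; `NULL` takes
#'   the mode default (0.02 square, 0.25 turbine).
#' @param exp_floor Source target pressure during expiration, cmH2O gauge;
#'   `NULL` takes the mode default (PEEP_set square, 0 turbine).
#' @param jitter_phi AR(1) coefficient of the per-breath PIP offsets, in
#'   `[0, 1)`; `NULL` takes the mode default.
#' @param jitter_sd Innovation SD of the per-breath PIP offsets, cmH2O;
#'   `NULL` takes the mode default.
#' @param noise_sd_pressure,noise_sd_flow Gaussian measurement noise SD
#'   added to the emitted pressure (cmH2O) and flow (mL/s) traces.
#' @param rate Emission/integration rate, Hz (>= 50).
#' @param seed Integer seed; the whole simulation is deterministic given it.
#' @return A `vent_source_params` list.
#' @export
vent_source_params <- function(mode = c("square", "turbine"),
                               PIP_set = 11, PEEP_set = 3,
                               RR_set = 40, IE_set = 1,
                               tau_up = NULL, tau_down = NULL,
                               exp_floor = NULL,
                               jitter_phi = NULL, jitter_sd = NULL,
                               noise_sd_pressure = 0.05, noise_sd_flow = 0.2,
                               rate = 100, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(PIP_set >= PEEP_set, PEEP_set >= 0, RR_set > 0, IE_set > 0,
            rate >= 50)
  defaults <- switch(mode,
    square  = list(tau = 0.02, floor = PEEP_set, phi = 0.93, sd = 0.072),
    turbine = list(tau = 0.25, floor = 0,        phi = 0.69, sd = 0.40))
  if (is.null(tau_up)) tau_up <- defaults$tau
  if (is.null(tau_down)) tau_down <- defaults$tau
  if (is.null(exp_floor)) exp_floor <- defaults$floor
  if (is.null(jitter_phi)) jitter_phi <- defaults$phi
  if (is.null(jitter_sd)) jitter_sd <- defaults$sd
  stopifnot(tau_up > 0, tau_down > 0, jitter_phi >= 0, jitter_phi < 1,
            jitter_sd >= 0, noise_sd_pressure >= 0, noise_sd_flow >= 0)
  structure(list(mode = mode, PIP_set = PIP_set, PEEP_set = PEEP_set,
                 RR_set = RR_set, IE_set = IE_set,
                 tau_up = tau_up, tau_down = tau_down, exp_floor = exp_floor,
                 jitter_phi = jitter_phi, jitter_sd = jitter_sd,
                 noise_sd_pressure = noise_sd_pressure,
                 noise_sd_flow = noise_sd_flow,
                 rate = rate, seed = as.integer(seed)),
            class = "vent_source_params")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

#' Stationary AR(1) per-breath PIP offsets
#'
#' Draws `b_k = phi * b_{k-1} + e_k`, `e_k ~ N(0, sd^2)`, with `b_1` from
#' the stationary distribution `N(0, sd^2/(1-phi^2))`, so the series is
#' stationary from the first breath. For this process the Poincare closed
#' forms are `SD1 = sigma_x*sqrt(1-phi)` and `SD2 = sigma_x*sqrt(1+phi)`
#' with `sigma_x^2 = sd^2/(1-phi^2)`.
#'
#' @param n Number of breaths (>= 1).
#' @param phi AR(1) coefficient in `[0, 1)`.
#' @param sd Innovation SD, cmH2O.
#' @param seed Integer seed; the draw is deterministic given it and does not
#'   disturb the caller's RNG state.
#' @return Numeric vector of n offsets.
#' @export
pip_jitter_series <- function(n, phi, sd, seed = 1L) {
  stopifnot(n >= 1)
  if (!is.finite(phi) || phi < 0 || phi >= 1) {
    stop("argument error: phi must lie in [0, 1)")
  }
  if (sd == 0) return(rep(0, n))
  with_seed(seed, {
    e <- stats::rnorm(n, 0, sd)
    b <- numeric(n)
    b[1L] <- stats::rnorm(1L, 0, sd / sqrt(1 - phi^2))
    if (n > 1L) for (k in 2:n) b[k] <- phi * b[k - 1L] + e[k]
    b
  })
}

#' Source pressure at a time within one cycle
#'
#' First-order source waveform in cycle time: during the set inspiratory
#' time `T_i = IE_set/(1+IE_set) * 60/RR_set` pressure relaxes from
#' `P_start` toward the (jittered) peak `PIP_k` with `tau_up`; during
#' expiration it relaxes from its end-inspiratory value toward `exp_floor`
#' with `tau_down`. Square mode is the same shape with small time constants
#' and `exp_floor = PEEP_set`; in the limit `tau_up -> 0` mid-inspiration
#' pressure is exactly `PIP_k`.
#'
#' @param t_in_cycle Time(s) within the cycle, `0 <= t < 60/RR_set`.
#' @param params A [vent_source_params()].
#' @param PIP_k Peak pressure target for this breath, cmH2O.
#' @param P_start Source pressure at cycle start, cmH2O (default
#'   `PEEP_set`, the steady state of a square source).
#' @return Source pressure(s), cmH2O.
#' @export
source_pressure <- function(t_in_cycle, params, PIP_k = params$PIP_set,
                            P_start = params$PEEP_set) {
  stopifnot(inherits(params, "vent_source_params"))
  T_cyc <- 60 / params$RR_set
  if (any(t_in_cycle < 0) || any(t_in_cycle >= T_cyc)) {
    stop("argument error: t_in_cycle must lie in [0, ", T_cyc, ")")
  }
  T_i <- params$IE_set / (1 + params$IE_set) * T_cyc
  p_end <- PIP_k - (PIP_k - P_start) * exp(-T_i / params$tau_up)
  ifelse(t_in_cycle < T_i,
         PIP_k - (PIP_k - P_start) * exp(-t_in_cycle / params$tau_up),
         params$exp_floor + (p_end - params$exp_floor) *
           exp(-(t_in_cycle - T_i) / params$tau_down))
}

#' Simulate a lung-ventilator circuit
#'
#' Integrates the single-compartment lung against the chosen pressure source
#' through the circuit's valve logic and emits everything a real recording
#' session would produce — plus the ground truth a real session cannot.
#'
#' Valve logic per time step: the one-way inspiratory valve passes flow only
#' while the source exceeds alveolar pressure (`P_src > P_alv`, no backflow
#' into the source); the expiratory path opens only while the inspiratory
#' path is closed, and the PEEP valve stops expiratory flow once
#' `P_alv <= PEEP_set`. Within each set expiratory phase the three-way valve
#' latches to the expiratory side the first time the source falls below
#' alveolar pressure, and resets at the next set inspiration — the physical
#' two-position valve flips once per phase rather than chattering.
#'
#' Integration is fixed-step at the emission rate with per-step exact
#' first-order relaxation (source and alveolar pressure each relax toward a
#' target held constant over the step), which keeps the emitted flow samples
#' consistent with trapezoidal tidal-volume integration. A resolution guard
#' rejects configurations where the lung time constant RC is not covered by
#' at least 2 steps.
#'
#' Per-breath peak targets are `PIP_set + b_k` with AR(1) jitter `b_k`;
#' Gaussian measurement noise is added to the emitted flow and limb-pressure
#' traces only, while the returned common-pressure trace and ground-truth
#' table stay clean. Identical seeds give bit-identical output.
#'
#' @param lung A [lung_params()].
#' @param source A [vent_source_params()].
#' @param duration Simulated duration in seconds (>= 3 cycles).
#' @return A list:
#' \describe{
#'   \item{flow}{emitted flow trace, mL/s (noisy).}
#'   \item{insp_pressure, exp_pressure}{emitted limb pressure traces, cmH2O
#'     gauge (noisy): inspiratory limb sensor sees the source; the
#'     expiratory limb sensor sees alveolar pressure while the expiratory
#'     path is open and the trapped `PEEP_set` while the PEEP valve is
#'     closed.}
#'   \item{common_pressure}{clean true common-line pressure trace.}
#'   \item{flow_clean}{clean flow trace (no measurement noise).}
#'   \item{breaths}{ground-truth table, one row per complete cycle:
#'     `t_start`, `t_insp_end`, `t_end`, `T_insp`, `T_exp` (set phase
#'     times), `PIP_target` (jittered per-breath target), `PIP_true`
#'     (achieved peak common pressure), `PEEP_set`, `V_T` (inspired volume,
#'     mL), `V_exp` (expired volume, mL; equals `V_T` in steady state since
#'     no leak is modeled).}
#'   \item{lung, source, duration}{the inputs, for provenance.}
#' }
#' @export
simulate_vent <- function(lung, source, duration) {
  stopifnot(inherits(lung, "lung_params"),
            inherits(source, "vent_source_params"))
  T_cyc <- 60 / source$RR_set
  if (duration < 3 * T_cyc) {
    stop("argument error: duration must cover at least 3 cycles (",
         format(3 * T_cyc), " s)")
  }
  dt <- 1 / source$rate
  if (lung$R * lung$C < 2 * dt) {
    stop("argument error: lung time constant R*C = ", lung$R * lung$C,
         " s is under 2 integration steps; increase rate above ",
         ceiling(2 / (lung$R * lung$C)), " Hz")
  }
  T_i <- source$IE_set / (1 + source$IE_set) * T_cyc
  n_steps <- floor(duration / dt + 1e-9)
  n_cycles <- ceiling(duration / T_cyc) + 1L
  jitter <- pip_jitter_series(n_cycles, source$jitter_phi, source$jitter_sd,
                              seed = source$seed)
  PIP_k <- source$PIP_set + jitter

  tt <- (seq_len(n_steps) - 1L) * dt
  p_src_out <- numeric(n_steps)
  p_exp_out <- numeric(n_steps)
  p_common <- numeric(n_steps)
  flow_out <- numeric(n_steps)
  vt_cycle <- numeric(n_cycles)
  vexp_cycle <- numeric(n_cycles)

  # inner sub-steps resolve the fastest time constant so that the emitted
  # samples lie on a smooth trajectory consistent with trapezoidal V_T
  tau_min <- min(source$tau_up, source$tau_down, lung$R * lung$C)
  n_sub <- max(5L, ceiling(dt / (tau_min / 5)))
  dt_in <- dt / n_sub
  decay_lung <- exp(-dt_in / (lung$R * lung$C))
  decay_up <- exp(-dt_in / source$tau_up)
  decay_down <- exp(-dt_in / source$tau_down)

  P_src <- source$exp_floor
  P_alv <- source$PEEP_set
  exp_latched <- FALSE
  cur_cycle <- 0L

  for (i in seq_len(n_steps)) {
    t <- tt[i]
    k <- floor(t / T_cyc + 1e-12) + 1L
    t_in <- t - (k - 1L) * T_cyc
    in_insp <- t_in < T_i - 1e-12
    if (k != cur_cycle) {
      cur_cycle <- k
      exp_latched <- FALSE
    }
    if (!in_insp && P_src <= P_alv) exp_latched <- TRUE
    insp_open <- (P_src > P_alv) && !(!in_insp && exp_latched)
    exp_open <- !insp_open && P_alv > source$PEEP_set + 1e-12

    # emit the instantaneous state at t
    flow_out[i] <- if (insp_open) (P_src - P_alv) / lung$R
                   else if (exp_open) -(P_alv - source$PEEP_set) / lung$R
                   else 0
    p_src_out[i] <- P_src
    p_exp_out[i] <- if (exp_open) P_alv else source$PEEP_set
    p_common[i] <- if (insp_open) P_src else max(P_alv, source$PEEP_set)

    # advance state from t to t + dt
    for (j in seq_len(n_sub)) {
      tj <- t + (j - 1L) * dt_in
      kj <- floor(tj / T_cyc + 1e-12) + 1L
      tj_in <- tj - (kj - 1L) * T_cyc
      in_insp_j <- tj_in < T_i - 1e-12
      if (kj != cur_cycle) {
        cur_cycle <- kj
        exp_latched <- FALSE
      }
      if (!in_insp_j && P_src <= P_alv) exp_latched <- TRUE
      insp_open_j <- (P_src > P_alv) && !(!in_insp_j && exp_latched)

      if (insp_open_j) {
        P_alv_new <- P_src + (P_alv - P_src) * decay_lung
        vt_cycle[kj] <- vt_cycle[kj] + lung$C * (P_alv_new - P_alv)
      } else if (P_alv > source$PEEP_set + 1e-12) {
        P_alv_new <- source$PEEP_set +
          (P_alv - source$PEEP_set) * decay_lung
        vexp_cycle[kj] <- vexp_cycle[kj] + lung$C * (P_alv - P_alv_new)
      } else {
        P_alv_new <- P_alv
      }
      target <- if (in_insp_j) PIP_k[kj] else source$exp_floor
      decay <- if (in_insp_j) decay_up else decay_down
      P_src <- target + (P_src - target) * decay
      P_alv <- P_alv_new
    }
  }

  noise <- with_seed(source$seed + 1L, list(
    flow = stats::rnorm(n_steps, 0, source$noise_sd_flow),
    insp = stats::rnorm(n_steps, 0, source$noise_sd_pressure),
    exp = stats::rnorm(n_steps, 0, source$noise_sd_pressure)
  ))

  n_complete <- floor(duration / T_cyc + 1e-9)
  ks <- seq_len(n_complete)
  pip_true <- vapply(ks, function(k) {
    sel <- tt >= (k - 1L) * T_cyc - 1e-12 & tt < k * T_cyc - 1e-12
    max(p_common[sel])
  }, 0)
  breaths <- data.frame(
    t_start = (ks - 1L) * T_cyc,
    t_insp_end = (ks - 1L) * T_cyc + T_i,
    t_end = ks * T_cyc,
    T_insp = T_i,
    T_exp = T_cyc - T_i,
    PIP_target = PIP_k[ks],
    PIP_true = pip_true,
    PEEP_set = source$PEEP_set,
    V_T = vt_cycle[ks],
    V_exp = vexp_cycle[ks]
  )

  mk <- function(v, channel, units, label) {
    waveform_trace(tt, v, channel = channel, units = units,
                   source_label = label, nominal_rate = source$rate)
  }
  list(
    flow = mk(flow_out + noise$flow, "flow", "mL/s", "common"),
    insp_pressure = mk(p_src_out + noise$insp, "pressure", "cmH2O",
                       "inspiratory-limb"),
    exp_pressure = mk(p_exp_out + noise$exp, "pressure", "cmH2O",
                      "expiratory-limb"),
    common_pressure = mk(p_common, "pressure", "cmH2O", "common-true"),
    flow_clean = mk(flow_out, "flow", "mL/s", "common-true"),
    breaths = breaths,
    lung = lung, source = source, duration = duration
  )
}

#' Write a simulation to delimited-text files
#'
#' Emits the four traces and the ground-truth breath table as CSV plus a
#' provenance JSON with every parameter and the seed, in the same column
#' layout the readers expect.
#'
#' @param sim Result of [simulate_vent()].
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return The directory, invisibly.
#' @export
write_simulation <- function(sim, dir, prefix = "sim") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(trace, name, value_name) {
    df <- data.frame(time = trace$t, v = trace$v)
    names(df)[2L] <- value_name
    write_result_csv(df, file.path(dir, paste0(prefix, "_", name, ".csv")))
  }
  wr(sim$flow, "flow", "flow")
  wr(sim$insp_pressure, "pressure_insp", "pressure")
  wr(sim$exp_pressure, "pressure_exp", "pressure")
  wr(sim$common_pressure, "pressure_common_true", "pressure")
  write_result_csv(sim$breaths, file.path(dir, paste0(prefix, "_breaths.csv")))
  write_run_metadata(
    list(lung = unclass(sim$lung), source = unclass(sim$source),
         duration = sim$duration),
    file.path(dir, paste0(prefix, "_provenance.json")))
  invisible(dir)
}
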