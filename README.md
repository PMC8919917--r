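# ventbench

Breath-by-breath ventilator waveform analysis and crossover evaluation in R.

## What this is for

Low-cost emergency ventilators — built during the COVID-19 pandemic from
turbines, valve assemblies and CPAP tubing — need quantitative, desk-scale
evidence that they ventilate like the ICU machines they stand in for.
`ventbench` implements the analysis pipeline used to compare such a device
against a conventional pressure-controlled ventilator in a paired
(crossover) animal protocol, plus a lung–ventilator simulator so every
stage of the pipeline can be validated against known ground truth without
an animal, a sensor rig, or the original recordings.

It is aimed at biomedical engineers and physiologists who have (or can
simulate) time-stamped flow and airway-pressure recordings and want
per-breath mechanics, window summaries and paired statistics out the other
end.

## What it computes

* **Waveform ingestion** — delimited-text flow (slm, L/min or mL/s →
  mL/s) and pressure traces (cmH2O gauge, or absolute hPa referenced to a
  barometric baseline, 1 hPa = 1.01972 cmH2O), linearly resampled onto a
  shared uniform grid (default 100 Hz) over the overlap of their supports.
* **Dual-limb pressure fusion** — circuits that isolate the inspiratory
  and expiratory limbs with a three-way valve need two pressure sensors;
  the common-line ("airway") pressure is reconstructed by taking the
  inspiratory-limb sample during each flow-derived inspiration and the
  expiratory-limb sample during expiration (per-sample maximum as the
  flow-free fallback).
* **Per-breath mechanics** — inspiration onset at a flow threshold
  (default 5 mL/s with 50 ms debounce), inspiration end at the first
  downward zero crossing, expiration end at the next onset. Per breath:
  tidal volume `V_T = ∫ flow dt` over inspiration (trapezoidal), `T_insp`,
  `T_exp`, `I:E = T_insp/T_exp`, instantaneous respiratory rate
  `RR = 60/(T_insp+T_exp)`, `PIP = max` cycle pressure, `PEEP` = mean
  pressure over the final 10% of expiration.
* **Protocol windows** — 1-min samples every 10 min, means per window,
  delivery errors `ΔPIP = mean PIP − PIP_target`,
  `ΔPEEP = mean PEEP − PEEP_target`, and minute ventilation per kg.
* **Poincaré variability** — for per-breath series (PIP, PEEP):
  `SD1 = SD((x[n+1]−x[n])/√2)` (breath-to-breath, short-term) and
  `SD2 = SD((x[n+1]+x[n])/√2)` (long-term), sample SDs about their own
  means, pairs formed only within contiguous analysis windows.
* **Crossover statistics** — Shapiro–Wilk-gated paired comparisons
  (paired t when the differences pass the gate at α, otherwise an exact
  two-tailed Wilcoxon signed-rank by sign-flip enumeration), two-tailed
  Mann–Whitney U for unpaired groups, and the paired-design sample size by
  noncentral-t power iteration. Histology (four 0–4 injury grades averaged
  into an overall score) and wet/dry weight-ratio arithmetic are included
  for the measured outcomes a desk analysis can't reproduce.
* **Simulator** — a single-compartment lung (`P_alv = V/C`,
  `dV/dt = (P_aw − P_alv)/R`) driven by a square (regulator) or turbine
  (first-order spin-up/spin-down) pressure source through one-way-valve and
  PEEP-valve logic, with stationary AR(1) breath-to-breath PIP jitter and
  Gaussian sensor noise; emits both limb pressures, flow, the clean
  common-line pressure and a ground-truth breath table, deterministically
  per seed.

## Worked example

Simulate one subject ventilated by an ICU-style square source and by a
turbine source at identical settings (PIP 11 cmH2O, PEEP 3 cmH2O,
40 breaths/min, set I:E 1:1), then analyze the emitted recordings:

```r
library(ventbench)
lung <- lung_params()                        # C = 2 mL/cmH2O, R = 0.1 cmH2O·s/mL
icu  <- vent_source_params("square",  seed = 1)
ceev <- vent_source_params("turbine", seed = 2)
sim_icu  <- simulate_vent(lung, icu,  duration = 62)
sim_ceev <- simulate_vent(lung, ceev, duration = 62)

br_icu  <- analyze_breaths(sim_icu$flow,  sim_icu$common_pressure)
br_ceev <- analyze_breaths(sim_ceev$flow, sim_ceev$common_pressure)
round(colMeans(br_icu [, c("V_T", "IE", "RR_inst", "PIP", "PEEP")]), 3)
#>     V_T      IE RR_inst     PIP    PEEP
#>  15.395   1.000  40.000  11.122   3.220
round(colMeans(br_ceev[, c("V_T", "IE", "RR_inst", "PIP", "PEEP")]), 3)
#>     V_T      IE RR_inst     PIP    PEEP
#>  13.220   0.850  39.988  10.722   3.196
```

Both sources deliver comparable volumes, pressures and rates, but the
turbine's spin-up delays the onset of inspiratory flow, so its *measured*
I:E (0.85) falls below the set 1:1 while the square source stays at 1.00 —
the same direction seen when a real turbine-driven emergency ventilator is
compared against an ICU machine. The turbine's breath-to-breath PIP
variability is likewise larger:

```r
poincare_sd(br_ceev$PIP, label = "PIP")
#> <poincare_result> PIP: SD1 = 0.3237, SD2 = 0.7129 (40 lag-1 pairs)
```

And the paired-design sample size at a mean paired difference of 10 (SD of
differences 5), 80% power, two-sided α = 0.05:

```r
paired_sample_size(delta = 10, sigma_d = 5, power = 0.8, alpha = 0.05)
#> [1] 5
```

For a full two-ventilator, multi-subject crossover — per-subject breath
tables, window summaries, Poincaré results and the group comparison table
with the gated paired tests — assemble a config and call
`run_crossover_report()` (see `?run_crossover_report`).

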