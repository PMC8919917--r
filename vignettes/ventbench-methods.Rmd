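---
title: "Methods: breath-by-breath ventilator evaluation and its simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: breath-by-breath ventilator evaluation and its simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ventbench)
```

## Scope and model of the data

`ventbench` evaluates a mechanical ventilator from its recorded waveforms.
The measurement setting it assumes: a pressure-controlled ventilator
connected to a passive (paralyzed, non-triggering) subject; a proximal
flow sensor on the common line; and either one airway pressure sensor or —
when a three-way valve isolates the inspiratory and expiratory limbs, as
in turbine-driven emergency circuits — one barometric sensor per limb.
Recordings arrive as delimited text with one time and one value column
per file.

Everything downstream works in two canonical units fixed at ingestion:
flow in mL/s (1 slm = 1 L/min = 1000/60 mL/s) and pressure in cmH2O gauge.
Absolute barometric recordings are referenced to atmosphere by subtracting
a baseline — the median over a user-chosen quiescent window, or an
explicit value — and scaling by 1.01972 cmH2O/hPa. The median is used
rather than the mean so a stray transient inside the baseline window
cannot shift the reference.

### Time alignment

Flow and pressure sensors have independent clocks and rates, so every
recording is linearly interpolated onto one uniform grid covering the
overlap of the traces' supports. The grid is half-open
`[t_start, t_end)` — the last grid point lies strictly before the end of
the overlap — so no trace is ever extrapolated. The default analysis rate
is 100 Hz: above the nominal rate of both sensor families, and ample to
resolve breath morphology at respiratory rates up to 120/min (≥ 25
samples per phase). Recordings are assumed to start simultaneously unless
their time columns share an absolute clock; there is no cross-correlation
clock recovery.

## Breath segmentation

The segmentation rule is deliberately simple and fully recorded in run
metadata, because detection conventions are exactly the kind of unstated
analysis choice that makes waveform results hard to reproduce:

* **Inspiration onset**: flow rises above `theta_on` (default 5 mL/s)
  after having been at or below it for at least `debounce` (default
  50 ms). The debounce rejects re-crossings during the decaying tail of
  inspiratory flow.
* **Inspiration end**: the first downward zero crossing of flow after
  onset.
* **Expiration end**: the next inspiration onset, so the post-expiratory
  pause belongs to expiration — this is what makes `RR_inst =
  60/(T_insp+T_exp)` an actual cycle rate.
* Cycles shorter than `min_cycle` (default 200 ms), cycles without a zero
  crossing, and the leading/trailing partial cycles are discarded. A
  consequence worth knowing: `n` onsets yield `n − 1` complete breaths,
  because the final cycle has no closing onset.

Tidal volume is the trapezoidal integral of flow over
`[t_start, t_insp_end)`, clipped below at zero. The right end of the
interval is closed by flat extension of the last inspiratory sample
rather than by interpolating toward the sample that marks the zero
crossing — that sample already contains expiratory flow, and interpolating
into it would leak the expiratory spike into the inspired volume.

PIP is the maximum pressure over the cycle. PEEP is the mean pressure
over the final 10% of expiration (minimum 3 samples) rather than the
cycle minimum: the minimum of a noisy trace is biased low by exactly the
noise the mean suppresses.

## Protocol windows and aggregation

The crossover protocol samples 1 min of waveform at the start of
ventilation and every 10 min thereafter (`protocol_windows()`, schedule
configurable). Window summaries are arithmetic means over the breaths
lying fully inside the window — breaths straddling an edge belong to no
window, avoiding double counting — plus the delivery errors
`ΔPIP = mean PIP − PIP_target` and `ΔPEEP = mean PEEP − PEEP_target`, and
minute ventilation `(Σ V_T / window minutes) / mass`. Aggregation order
across a recording: per-subject value = mean of window means, then group
statistics across subjects. Where a recording is shorter than one window,
a single window spanning the whole recording is used.

## Poincaré SD1/SD2

For an ordered per-breath series, each value is paired with its immediate
successor; SD1 and SD2 are the sample standard deviations of the rotated
coordinates `(x[n+1] − x[n])/√2` and `(x[n+1] + x[n])/√2`, each about its
own mean. Conventions chosen here, all recorded in provenance:

* **Sample (n−1) rather than population SD** — windows contribute few
  pairs, and the sample form keeps SD1² + SD2² equal to the sum of the
  lagged sample variances (the ellipse identity the tests assert).
* **Mean-free SD2** — subtracting the mean of the sum coordinate makes
  constant offsets change neither statistic; the alternative (RMS about
  the origin) would fold the series mean into "long-term variability".
* **No pairs across window gaps** — values separated by a 9-min
  unanalyzed gap are not "immediate successors"; pairs are formed within
  contiguous windows only and pooled. Both choices (gap-spanning and
  within-window) are easy to compute; within-window is the default
  because it is the only reading under which SD1 measures breath-to-breath
  change throughout.

For a stationary AR(1) series with coefficient φ and marginal variance
σ², SD1 → σ√(1−φ) and SD2 → σ√(1+φ); white noise gives SD1 ≈ SD2. These
closed forms are the oracle for the variability tests.

## The statistical battery

Paired comparisons follow a normality-gated design: Shapiro–Wilk on the
paired differences at the same α as the main test (0.05 by default; the
gate level is otherwise unstated in such protocols, and using one α keeps
a single interpretable error rate), then a two-tailed paired t-test when
the gate passes, otherwise a two-tailed exact Wilcoxon signed rank.
Zero differences are dropped (standard signed-rank convention); the exact
p comes from full sign-flip enumeration over midranks for up to 15
non-zero differences — so ties in magnitude still get an exact p —
falling back to the tie-corrected normal approximation above that.
Simulation under the null (normal differences, n = 5) puts the gated
procedure's type-I error at 0.05 ± 0.02, which the suite asserts: at
n = 5 the signed-rank branch can never reject at α = 0.05 (its smallest
two-sided p is 0.0625), so the gate trims, not inflates, the error rate.

Degenerate input — all differences exactly zero, which identical input
files produce — yields p = 1 with a warning flag rather than an error,
so a sanity-check run of the crossover report on duplicated recordings
completes and labels itself.

Unpaired groups use the two-tailed Mann–Whitney U: exact for combined
n ≤ 20 without ties, otherwise the tie-corrected normal approximation.

The paired-design sample size iterates two-sided noncentral-t power over
n: with `n` differences of mean δ and SD σ_d, power is the probability
that |T| with n−1 df and noncentrality (δ/σ_d)√n exceeds the central-t
critical value. The noncentral-t formulation, not the normal
approximation, is used because it is the exact small-sample answer — at
δ/σ_d = 2, power 0.8, α 0.05 it requires n = 5 (power 0.909 at n = 5,
0.755 at n = 4), which is the crossover protocol's own determination.

Histology scoring (four 0–4 injury grades averaged into an overall
score) and wet/dry weight ratios are plain arithmetic over user-supplied
tables: these outcomes are measured, not desk-reproducible, and enter the
package only through that arithmetic and the battery above.

## The simulator

The synthetic-data generator exists so that segmentation, fusion,
variability and the crossover statistics can each be validated against
known ground truth. It is a single-compartment linear lung,
`P_alv = (V − V_rest)/C`, `dV/dt = (P_aw − P_alv)/R`, driven through
valve logic by one of two pressure sources:

* **square** — a regulator-driven ICU-style source: first-order
  transitions with small time constants (default 0.02 s) between the set
  pressures, and the source itself holds PEEP during expiration
  (`exp_floor = PEEP_set`).
* **turbine** — a blower with finite spin-up/spin-down (default
  `tau_up = tau_down = 0.25 s`). During expiration the turbine is
  actively braked and its pressure collapses toward atmosphere
  (`exp_floor = 0`); PEEP is then maintained by the spring-loaded PEEP
  valve, not by the source. This split matters: a source that decayed
  only to PEEP would re-open the inspiratory valve mid-expiration against
  the emptied lung, and would give no inspiratory-onset delay — it is the
  spin-up from near-zero that forces source pressure to climb past the
  lung's PEEP before flow can start, delaying the detected onset and
  lowering the *measured* I:E below the set ratio, exactly the turbine
  signature the analysis pipeline is meant to detect. At the default time
  constants and study settings the measured I:E comes out near 0.85
  versus 1.00 for the square source; the in-vivo gap for a real device is
  larger still, since a motor is not a clean first-order system.

**Valve logic.** The one-way inspiratory valve passes flow only while
`P_src > P_alv` (no backflow into the source); the expiratory path opens
only while the inspiratory path is closed; the PEEP valve stops
expiratory flow once `P_alv ≤ PEEP_set`, idealized as instantaneous
closure without spring hysteresis. Within each set expiratory phase the
three-way valve latches to the expiratory side the first time the source
drops below the lung, and resets at the next set inspiration: the
physical two-position diaphragm flips once per phase, and the latch keeps
the idealized valve from chattering when source and lung pressures cross
repeatedly during a slow spin-down.

**Breath-to-breath variability.** Per-breath peak targets are
`PIP_set + b_k` with `b_k` a stationary AR(1) series (first value drawn
from the stationary distribution). The mode defaults are fixed, once,
from the Poincaré variability characteristic of each source class —
turbine φ = 0.69, innovation SD 0.40 cmH2O (implying SD1 ≈ 0.31,
SD2 ≈ 0.72 cmH2O); square φ = 0.93, innovation SD 0.072 cmH2O (implying
SD1 ≈ 0.052, SD2 ≈ 0.27 cmH2O) — via the closed forms above. A
regulator's tiny, slowly wandering errors are high-φ/low-SD; a turbine's
cycle-to-cycle current differences are lower-φ/higher-SD.

**Noise.** Gaussian measurement noise is added to the emitted flow and
limb-pressure traces only (defaults 0.2 mL/s and 0.05 cmH2O); the
returned common-pressure trace and ground-truth table stay clean. The
flow-noise default keeps the onset threshold at 25 noise SDs, making a
noise-triggered spurious onset (which the debounce alone cannot always
reject once the decaying inspiratory tail has dipped below threshold)
vanishingly rare at desk-scale durations.

**Lung defaults.** C = 2 mL/cmH2O, R = 0.1 cmH2O·s/mL — an intubated
rabbit-sized respiratory system whose resistance is dominated by a 3 mm
endotracheal tube. The resulting RC = 0.2 s matters for realism of the
*measured* quantities: inspiratory flow then decelerates through, but
persists to the end of, a 0.75 s inspiration, as real recordings show.
With a much smaller RC, flow decays to the noise floor mid-inspiration
and any zero-crossing detector ends inspiration there.

**Integration.** Fixed-step at the emission rate, with the source and
alveolar pressures advanced by exact first-order relaxation over each
step, subdivided internally so the fastest time constant is covered by at
least five sub-steps (and never fewer than five sub-steps per sample). The
exact-relaxation update was chosen over forward Euler deliberately: the
emitted flow samples must be consistent with trapezoidal tidal-volume
integration, and at 100 Hz a forward-Euler trajectory biases the measured
V_T by several percent against the ground-truth delivered volume, an
artifact of the integrator rather than of the physics. A guard rejects
configurations whose lung time constant RC is not covered by at least two
emission steps, directing the user to a higher rate. Ground-truth inspired
and expired volumes are accumulated from the state trajectory itself, so
volume conservation (no leak is modeled) holds to machine precision in
steady state, and the trapezoidal estimate can be judged against truth:
at the defaults it agrees within 0.5%; when RC approaches the sampling
interval (e.g. R = 0.02, RC = 0.04 s at 100 Hz) the measured V_T reads
2–3% low because the onset peak is under-sampled — the ground-truth table
is the reference in that regime.

## What the simulator does and does not emulate

Emulated, with ground truth: square vs sawtooth waveform shape, the
turbine's onset delay and lowered measured I:E, per-breath PIP jitter
with distinct short- and long-term structure, one-way and PEEP-valve
behavior, dual-limb sensor placement (inspiratory limb sees the source,
expiratory limb sees the lung during expiration and the trapped PEEP
otherwise), and sensor noise.

Not emulated: spontaneous respiratory effort and triggering (the intended
subject is paralyzed), nonlinear or two-compartment mechanics, leaks,
secretions and motion artifacts, sensor drift and clock skew between
recordings, gas exchange (oxygenation and CO2 are measured quantities,
not computable from mechanics), and the internal control loop of a real
ICU ventilator. Passing the simulator-based suite therefore shows the
pipeline is correct under its stated assumptions — it does not show the
detection thresholds are optimal for any particular real recording,
which is why every threshold is configurable and recorded in provenance.

## Numerical conventions and degenerate inputs

* Unit conversions are exact linear maps; slm → mL/s → slm round-trips to
  machine precision.
* Grids are half-open; phase gating uses `[start, end)` so fusion covers
  each sample exactly once; the fusion switch at phase boundaries is
  instantaneous, with no cross-fade, so a boundary discontinuity remains
  visible as a segmentation diagnostic.
* Interpolation never extrapolates; alignment requires ≥ 1 s of overlap.
* Zero flow throughout yields zero breaths (not an error); all-zero
  paired differences yield p = 1 with a warning; an empty protocol window
  yields a flagged-empty summary excluded from downstream means.
* Simulations are bit-identical given a seed, and the jitter/noise draws
  restore the caller's RNG state.

## Problem sizes in the test suite

The suite validates at desk scale: 31–62 s simulations for per-breath
properties (40+ cycles at 40 breaths/min), 310 s two-ventilator
crossover fixtures with five synthetic subjects and a 1-min window every
2 min, AR(1) series of 10^4 for the closed-form variability checks, and
2000 replicates for the null calibration of the gated paired test. These
sizes give the asserted tolerances comfortable margins while keeping the
whole suite to a few minutes.

## Known limitations

* The turbine model is a first-order stand-in for a motor with inertia;
  it reproduces the direction and rough scale of the measured-I:E
  depression, not any particular device's magnitude.
* PEEP-valve closure is ideal; real spring valves flutter near closure,
  which slightly inflates measured PEEP variability on real recordings.
* The fallback per-sample-maximum fusion rule is only correct when the
  disconnected limb reads below the common line, which holds for the
  intended circuit but not for arbitrary plumbing.
* Segmentation assumes mandatory ventilation of a passive subject;
  spontaneous efforts would need trigger-aware onset detection.
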