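Package: ventbench
Title: Breath-by-Breath Ventilator Waveform Analysis and Crossover Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for desk-scale evaluation of mechanical ventilators from
    recorded flow and pressure waveforms. Reads and time-aligns delimited-text
    sensor recordings, fuses dual-limb barometric pressure traces into a single
    airway pressure waveform, segments flow into respiratory cycles and derives
    per-breath mechanics (tidal volume, inspiratory:expiratory ratio, peak
    inspiratory and end-expiratory pressures, respiratory rate), computes
    Poincare SD1/SD2 variability of per-breath pressure series, and runs the
    paired statistical battery appropriate for a two-ventilator crossover
    design, including a noncentral-t sample-size calculation. A configurable
    single-compartment lung-ventilator simulator with square (regulator) and
    turbine pressure sources, one-way valve and PEEP-valve logic, and
    breath-to-breath AR(1) pressure jitter generates synthetic recordings with
    ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
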