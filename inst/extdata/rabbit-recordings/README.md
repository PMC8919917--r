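# Deposited rabbit recordings (not shipped)

The crossover reproduction check in `tests/testthat/test-acceptance.R`
analyzes the per-rabbit flow and pressure waveform recordings deposited as
the study's supplementary data files. They are too large to ship inside the
package, so this directory holds only this note.

To run the reproduction:

1. Download the supplementary waveform files (per-rabbit flow recordings
   for both ventilators, and the pressure recordings) and place them here
   as delimited text.
2. Write a `config.yaml` in this directory following the
   `run_crossover_report()` schema documented in `?run_crossover_report`,
   with ventilator labels `carestation` and `falcon`, one subject entry
   per rabbit (`MV1` .. `MV5`, body mass in kg), and per-recording
   `flow`/`pressure`/`pressure_insp`/`pressure_exp` paths, column names and
   units matching the downloaded files (`flow_units: slm` for the proximal
   flow sensor; `pressure_units: hPa_absolute` plus a `baseline_window`
   for the barometric sensors).
3. Reinstall the package and run the test suite.
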