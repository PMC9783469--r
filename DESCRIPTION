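Package: pulseAlign
Title: Cardiac-Aligned Waveform Mapping for Fast fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Retrospective cardiac alignment of fast (simultaneous-multislice)
    fMRI time series to heartbeat peaks measured by photoplethysmography.
    Detects PPG peaks with autocorrelation-based cycle estimation, computes
    ultrashort-window RMSSD heart-rate variability, bins every slice's samples
    by time relative to the nearest heartbeat into sub-second cardiac-gated
    waveforms per voxel, scores test-retest reliability with a zero-referenced
    R-squared between even- and odd-beat averages, models the waveforms with a
    reliability-weighted singular value decomposition (cross-validated
    components, per-voxel beta weights, relative RMS error), and maps the
    cycle-fraction timing of blood and CSF pulsations. Includes arterial-zone
    region-of-interest aggregation and a synthetic-data generator that emits
    PPG traces and slice-timed 4D volumes with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite,
    RNifti,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'physio.R'
    'alignment.R'
    'model.R'
    'roi.R'
    'synthetic.R'
    'io.R'
    'pipeline.R'
    'pulseAlign-package.R'
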