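Package: PulseAttractor
Title: Attractor Reconstruction of Arterial Pulse Waveforms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Delay-coordinate (Takens) embedding of approximately periodic
    physiological waveforms such as arterial blood pressure or
    photoplethysmography signals. A three-dimensional trajectory built from
    time-lagged copies of the signal is projected onto the plane orthogonal
    to the (1,1,1) diagonal, separating baseline level (the u coordinate)
    from waveform morphology (the v,w plane). The resulting two-dimensional
    attractor is quantified into physiologically interpretable features:
    average cycle length and heart rate via a normalized autocorrelation,
    attractor size (proportional to pulse pressure), triangular rotation
    (downstroke concavity), arm widths and edge-density uniformity
    (beat-to-beat variability), a waveform-periodicity score, and baseline
    statistics. Includes a parametric in-silico pulse generator with
    controllable morphology, jitter, baseline wander and noise, sliding
    window feature tracking for long records, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'calibration.R'
    'waveform-io.R'
    'pulse-synth.R'
    'cycle.R'
    'embedding.R'
    'features.R'
    'track.R'
    'cli.R'
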