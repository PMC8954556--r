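Package: uwbreath
Title: Respiratory Motion Recovery and Classification from UWB Radar
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Recovers and classifies chest-wall respiratory motion from
    single-antenna ultra-wideband (UWB) impulse radar range-bin recordings
    contaminated by strong broadband interference, such as linac gantry motion
    during volumetric modulated arc therapy (VMAT) delivery. Provides a seeded
    synthetic radar-scene simulator emulating a respiratory motion phantom and
    treatment-room interference, multilayer-perceptron adaptive interference
    estimators driven by interference-only reference range bins (single-bin and
    range-bin variants), polarity-corrected power-weighted range-bin averaging,
    moving-average filtering, spectral breathing-rate estimation, and a
    four-class breathing-pattern classifier (no breathing, breath hold, free
    breathing, deep inspiration) based on windowed signal power with
    k-means-derived thresholds, together with a three-phase clinical workflow
    (noise-profile training, target localization, monitoring) and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'accessors.R'
    'classification.R'
    'enhancement.R'
    'mlp.R'
    'noise-estimation.R'
    'pipeline.R'
    'synthetic.R'
    'io.R'
    'cli.R'
    'uwbreath-package.R'
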