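Package: isoPRM
Title: Internal-Standard-Triggered Parallel Reaction Monitoring Simulation
    and Quantification
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A desk-scale simulator and quantification toolkit for
    internal-standard-triggered parallel reaction monitoring (IS-PRM,
    SureQuant-style) targeted proteomics. Provides tryptic assay panel
    design from protein sequences, synthetic liquid-chromatography and
    orbitrap signal generation across a wide dynamic range, a
    discrete-event model of the triggered acquisition duty cycle with a
    scheduled-PRM comparator, a Skyline-equivalent quantification chain
    (trace extraction, internal-standard-anchored integration boundaries,
    total-ion-current normalization, protein rollup and 0-100 rescaling),
    assay performance metrics (points per peak, retention-time stability,
    dynamic range), and five-parameter logistic immunoassay calibration
    with standard-curve validation rules for orthogonal validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
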