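Package: tvfc
Title: Temporal Variability of Dynamic Functional Connectivity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes the temporal variability of resting-state functional
    connectivity (FC) from parcellated BOLD time series. FC matrices are
    estimated in non-overlapping sliding windows over a multi-scale grid of
    window lengths and start offsets, and the variability of the regional,
    intra-network and inter-network FC pattern is summarised as one minus the
    mean between-window correlation of the vectorised pattern. Includes
    post-extraction preprocessing (initial-volume discard, Friston-24 motion
    expansion, nuisance regression, FFT band-pass filtering), framewise
    displacement quality control, covariate-adjusted group statistics (ANCOVA
    with Bonferroni-corrected post-hoc contrasts, Spearman clinical
    correlations), and a synthetic cohort generator with controllable
    time-varying covariance for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'parcellation.R'
    'io.R'
    'preprocess.R'
    'dynvar.R'
    'stats.R'
    'synthetic.R'
    'pipeline.R'
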