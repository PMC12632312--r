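Package: lymphchron
Title: Pressure-Induced Chronotropy Analysis for Collecting Lymphatic Vessels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying spontaneous contractile function of isolated
    collecting lymphatic vessels studied by pressure myography. Detects phasic
    contractions in inner-diameter traces, computes the standard contractile
    parameters (amplitude, normalized amplitude, ejection fraction, tone,
    fractional pump flow) per pressure step, fits the frequency-pressure
    relationship over the near-linear 0.5-5 cmH2O range (slope, intercept,
    r-squared, delta-F), and compares genotype or treatment groups with the
    field's standard tests (unpaired t, one-way ANOVA with Dunnett, repeated-
    measures ANOVA with Sidak). Ships a stochastic trace simulator with
    genotype presets so every pipeline stage is testable without raw
    recordings, plus helpers for single-cell RNA-seq cell QC filtering and
    per-cluster dot-plot expression statistics.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    mvtnorm,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    multcomp,
    jsonlite,
    optparse
Config/testthat/edition: 3
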