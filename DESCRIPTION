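Package: qeegnet
Title: Quantitative EEG Band Power, Source Connectivity and Brain Network
    Analysis for Randomized Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for quantitative electroencephalography (QEEG)
    endpoints in randomized trials: spectral band power in eight canonical
    bands with band ratios and occipital alpha peak frequency, standardized
    minimum-norm (sLORETA-style) source estimation onto 68 cortical regions
    of interest, functional connectivity by the imaginary part of coherency,
    density-thresholded binary brain networks with graph metrics including
    nodal characteristic path length and small-worldness, and the trial
    statistics layer (two-group tests, Benjamini-Hochberg false discovery
    rate control over region families, baseline-adjusted ANCOVA,
    covariate-adjusted regression, and chained-equation multiple imputation
    by predictive mean matching with Rubin pooling).  A synthetic-cohort
    generator with planted lagged connectivity effects, volume-conduction
    mixing, artifact injection, stratified permuted-block randomization and
    controlled missingness makes every stage testable without participant
    data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    signal,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
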