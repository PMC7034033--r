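Package: eegworkload
Title: EEG Band-Power Workload Indicators via Cross-Subject Consensus
    Feature Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for discovering a common cross-subject set of EEG spectral
    workload indicators from multi-channel recordings acquired under graded
    task-load conditions. Implements band-power feature extraction (windowed
    Hamming periodograms, baseline-relative normalization, engagement and
    task-load ratio indices), per-subject feature ranking by joint mutual
    information (with information-gain and t-statistic comparators), a
    rank-position consensus weighting scheme that pools per-subject top-10
    lists into a population-level feature set, linear-discriminant accuracy
    curves with a t-test stopping criterion, and a repeated-measures
    validation battery (Shapiro-Wilk gate, Friedman omnibus, Wilcoxon
    signed-rank post-hoc with Bonferroni correction). A seeded synthetic
    cohort generator emulating a four-condition teleoperation workload
    experiment makes the whole pipeline testable without acquisition
    hardware or access to confidential recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    MASS,
    signal,
    jsonlite,
    withr,
    BiocGenerics,
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
    'classification.R'
    'consensus.R'
    'feature-ranking.R'
    'io.R'
    'pipeline.R'
    'preprocessing.R'
    'spectral-features.R'
    'synthetic-data.R'
    'workload-stats.R'
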