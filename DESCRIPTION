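Package: NeuroPheno
Title: Multimodal Phenotyping Analytics for Early-Life-Pain Mouse Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Reusable analysis pipeline for the quantitative readouts of an
    optogenetic early-life-pain mouse study: multi-unit-activity detection on
    multi-electrode-array voltage traces (Butterworth highpass, robust noise
    estimation, 5x-SD threshold crossing, active-channel classification),
    Fura-2 ratiometric calcium-trace peak calling with run-length rules for
    capsaicin and high-K+ responses, IntelliCage visit/nosepoke/lick feature
    extraction including a shuffle-null repetitiveness log-ratio and
    compulsive-licking metrics, a group-statistics layer (pooled t-test,
    Mann-Whitney U, two-way repeated-measures ANOVA, Sidak and Monte-Carlo
    Dunnett posthoc, Benjamini-Hochberg FDR, Range/Auto scaling), and a
    volcano screen for lipid feature tables. Seeded synthetic-data generators
    for all four modalities provide ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite,
    yaml,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    mvtnorm,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'NeuroPheno-package.R'
    'accessors.R'
    'calcium.R'
    'feature-matrix.R'
    'intellicage.R'
    'io.R'
    'lipids.R'
    'mea.R'
    'pipeline.R'
    'simulate-calcium.R'
    'simulate-intellicage.R'
    'simulate-lipids.R'
    'simulate-mea.R'
    'stats.R'
    'utils.R'
    'validation.R'
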