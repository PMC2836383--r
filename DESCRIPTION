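Package: pathmarker
Title: Pathway Activity Scoring and Perturbation-Based Biomarker Discovery
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Computes per-sample molecular pathway activity levels (the mean
    expression of a pathway's measured member genes), ranks pathways by a
    permutation-calibrated perturbation score (the unsigned two-sample
    t-statistic on activity levels between two clinical classes), encodes
    samples by top-pathway activities, and evaluates single and integrated
    pathway/gene biomarker panels with leave-one-out cross-validated
    instance-based classification (AUC). Includes hierarchical clustering of
    activity-encoded samples with Newick export, readers and writers for the
    GMT, CLS, GCT and plain TSV expression formats, a synthetic two-class
    expression simulator with planted pathway effects, and a command-line
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
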