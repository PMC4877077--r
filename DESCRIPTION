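Package: gsanova
Title: Gene Set Analysis of Variance for Multi-Group Expression Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Detects gene sets enriched for expression changes across two or
    more sample groups (e.g. treatment time courses) by scoring each gene with
    the one-way ANOVA f-statistic, averaging f over set members, standardizing
    against random gene sets of the same size, and assessing significance with
    group-label permutations, a pooled global null, and q-values. Includes
    count-table / GMT / design-table readers, median-of-ratios library-size
    normalization with a log-scale variance-stabilizing transform,
    hierarchical-clustering sample outlier QC, temporal response-pattern
    (quadrant) classification of log fold-change pairs, qPCR relative copy
    number quantification, and a negative-binomial count simulator with known
    spike-in truth for calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    ape
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    DESeq2
Config/testthat/edition: 3
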