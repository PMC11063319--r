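Package: methdriver
Title: Methylation-Driven Gene Discovery from Paired Methylation and Expression Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies methylation-driven genes from paired DNA methylation
    (450K-style beta values) and gene expression microarray data. Implements
    differential methylation and expression screening with empirical-Bayes
    moderated t-statistics and adaptive mean + 2*sd effect thresholds,
    promoter-restricted CpG-gene integration by negative Spearman
    correlation over patient-matched samples, hypergeometric
    over-representation and single-CpG gene set enrichment analysis, and a
    weighted co-expression network stage (soft thresholding, topological
    overlap, module eigengenes, module-trait correlation). Includes a
    synthetic paired-data generator with planted ground truth for
    calibration and recovery validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr,
    fgsea
Config/testthat/edition: 3
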