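Package: heatmem
Title: Heat-Stress Transcriptional Memory Analysis for Priming Designs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of heat-stress priming and transcriptional memory in
    factorial RNA-seq designs (untreated, triggered, primed, and
    primed-then-triggered treatments across wild-type and mutant genotypes).
    Provides a transparent simplified negative-binomial Wald
    differential-expression core (median-of-ratios normalization,
    method-of-moments dispersion with trend shrinkage, two-group IRLS fits),
    type I and type II memory-gene classification with mutant dependence
    calls, global distribution-shift statistics (ECDF, two-sample
    Kolmogorov-Smirnov tests, compact letter displays), EASE-score gene
    ontology enrichment, one-to-one ortholog set overlaps, reference-gene
    stability ranking (geNorm, NormFinder-style, BestKeeper, comparative
    delta-Ct, RefFinder aggregation), comparative-Ct qPCR quantification,
    growth-rate phenotyping, and a synthetic-data generator that plants
    known memory-gene archetypes for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml,
    DESeq2,
    SummarizedExperiment
Config/testthat/edition: 3
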