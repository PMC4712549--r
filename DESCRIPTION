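Package: mirkd
Title: Fusion-Gene Knockdown miRNA Screening from TaqMan Array CT Data
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Differential microRNA expression screening from TaqMan low
    density array (LDA) threshold-cycle exports in two-group knockdown
    designs. Provides CT ingestion with "Undetermined" sentinel handling,
    cyclic LOESS normalization per array plate, an empirical-Bayes moderated
    t-test with Benjamini-Hochberg adjustment, detection-limit ("on/off")
    lower-bound fold changes, duplicate-assay concordance filtering,
    single-assay delta-delta-CT quantification with reference-stability
    ranking and Spearman cross-platform validation, direction-aware signed
    TargetScan-style context+ score aggregation of miRNA targets,
    hypergeometric/EASE gene-ontology enrichment, and seedable synthetic-data
    generators with ground-truth manifests for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    limma,
    jsonlite,
    withr
biocViews: GeneExpression, DifferentialExpression, Normalization,
    miRNA, qPCR, Software
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
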