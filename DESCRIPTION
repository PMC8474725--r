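Package: miRct
Title: Quality Control, Normalization and Differential Analysis of miRNA
    PCR Array Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis of miRNA RT-qPCR array experiments in the
    384-well miScript plate format (372 miRNA assays plus 12 control wells).
    Provides plate-level input parsing and multi-plate merging, sample quality
    control based on missing-value fractions and the reverse-transcription
    control versus positive PCR control comparison, delta-Ct normalization
    against endogenous (snoRNA/snRNA) or exogenous (cel-miR-39 spike-in)
    controls, per-miRNA differential expression with empirical-Bayes moderated
    t-statistics and Benjamini-Hochberg correction, offline miRNA-to-target
    gene mapping, hypergeometric over-representation analysis against GMT
    gene-set collections, a seeded plate simulator with known ground truth,
    and an automated run report.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml,
    pheatmap,
    tools
Suggests:
    testthat (>= 3.0.0),
    limma,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'plate-io.R'
    'qc.R'
    'normalize.R'
    'de.R'
    'clustering.R'
    'targets.R'
    'enrichment.R'
    'miRct-package.R'
    'simulate.R'
    'pipeline.R'
    'report.R'
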