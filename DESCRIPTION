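Package: tigsmm
Title: Transcriptome-Integrated Genome-Scale Metabolic Modeling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Constraint-based analysis of genome-scale metabolic models
    (GSMMs) with transcriptome integration. Reads and writes metabolic
    models (SBML Level 3 FBC v2 and a tabular dialect), solves flux
    balance analysis (FBA) problems, integrates FPKM expression data via
    the GIMME algorithm (minimal penalized absolute flux subject to a
    growth requirement, with a percentile expression threshold),
    classifies active reactions across culture conditions, and
    identifies reporter metabolites from gene-level differential
    statistics using directional Z-score aggregation with a sampled
    background correction. Includes a synthetic-data generator producing
    feasible toy networks, FPKM tables, and gene statistics so the whole
    pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
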