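Package: miRCombo
Title: Synergy, Target-Overlap and Survival Analyses for Tumor-Suppressor
    miRNA Combinations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies synergy of miRNA mimic combinations from live-cell
    growth curves with linear-interaction and Bliss combination indices;
    builds multi-study differential-expression consensus sets and tests
    miRNA-target enrichment by hypergeometric and seeded permutation nulls;
    relates silencing magnitude to targeting-miRNA count and binding-site
    burden; clusters miRNA families on shared predicted targets; scans
    transcripts for canonical seed sites (8mer, 7mer-m8, 7mer-A1); and
    stratifies patient survival by average miRNA expression z-score. A
    synthetic-data generator with planted ground truth makes every stage
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    ape,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'cluster.R'
    'overlap.R'
    'dose.R'
    'io.R'
    'survival.R'
    'synth.R'
    'sites.R'
    'synergy.R'
    'pipeline.R'
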