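Package: pathconverge
Title: Cross-Condition Pathway Convergence Analysis for Proteomics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: An integrative differential-abundance pipeline for multi-model
    proteomics studies of insulin resistance and similar designs. Provides
    group-wise missing-value filtering, k-nearest-neighbour imputation and
    rank-stability reference normalisation; empirical-Bayes moderated t-tests
    with Benjamini-Hochberg false discovery rate control; z-score direction
    analysis across two or three experimental models; mean-rank gene-set
    enrichment; Fisher's-method integration of per-condition pathway p-values
    into combined z-scores with convergence selection; and cohort
    pathway-phenotype Pearson correlation screening with tertile
    stratification and Mann-Whitney comparisons. A seeded synthetic-study
    generator with planted pathway effects makes every stage testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
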