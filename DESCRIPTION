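Package: exomeburden
Title: Gene-Based Burden Tests, Weighted Meta-Analysis and Familial
    Relative Risk Decomposition for Rare Coding Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Gene-level association analysis of rare coding variants in
    case-control sequencing studies.  Classifies annotated variants into
    protein-truncating and rare missense categories (with a
    nonsense-mediated-decay escape rule for truncating variants near the
    3' end of a transcript), collapses genotypes to per-gene carrier
    indicators, tests carrier status against a family-history-weighted
    disease phenotype by reversed logistic regression, combines studies
    with anchor-gene-weighted z-score meta-analysis, and decomposes the
    familial relative risk attributable to protein-truncating variants
    with an empirical-Bayes mixture model over gene effect sizes.
    Includes a cohort and pedigree simulator that reproduces the
    statistical structure assumed by every stage, so the full pipeline
    is testable without access-controlled data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    pracma,
    yaml,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
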