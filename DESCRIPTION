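Package: herborgan
Title: Target-Organ Localization for Herbal Compound Target Sets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A pipeline for locating the target organs of a medicinal herb
    from its compound table and multi-source compound-target associations.
    Compounds are screened by oral bioavailability and drug-likeness,
    per-source confidence rules yield a deduplicated target union, core
    targets are selected from a score-filtered protein-protein interaction
    network by a degree rule, and organs are ranked two ways: gene-set
    enrichment/depletion against a gene-organ catalog (classical, EASE and
    mid-p hypergeometric tests with Benjamini-Hochberg correction) and
    expression-atlas linking (above-mean and positive Z-score rules,
    consensus maxima across atlases, highest-expression organ-group
    assignment). Bipartite and tripartite compound-gene-organ networks are
    assembled and exported, and a synthetic-data module generates every
    input class with known planted truth for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
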