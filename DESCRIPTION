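Package: sfpage
Title: Gene-Age Structured Analysis of Seminal Fluid Protein Repertoires
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing how evolutionary gene age structures the
    functional and evolutionary properties of a seminal-fluid-protein (Sfp)
    gene set. Assembles a high-confidence catalog from two candidate lists,
    attaches phylostratigraphic age classes and cross-validates them against
    independent ortholog calls, tests age-class composition against genome-wide
    background proportions with post hoc residual tests, computes the tau
    tissue-specificity index and male-reproductive-gland-specific calls from a
    genes-by-tissues expression matrix, builds a high-confidence
    protein-protein interaction network from per-channel confidence scores
    (excluding text mining), partitions interaction degree within and outside
    the Sfp set, extracts size-filtered subnetworks and runs Monte Carlo
    resampling tests for age-class enrichment and reproductive-function
    association, and decomposes per-gene McDonald-Kreitman statistics into
    adaptive and nonadaptive rates with a site-frequency-spectrum threshold
    correction. Ships seeded synthetic-data generators with known ground truth
    for every input class so the full pipeline runs and is validated offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
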