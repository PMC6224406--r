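Package: regdriver
Title: Recurrence Testing of Somatic Mutations in Gene-Regulatory Regions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovery of candidate non-coding driver mutations in tumour
    cohorts. Defines promoter windows and promoter-interacting cis-regulatory
    elements (CREs) from capture Hi-C style interaction tables, fits a
    covariate-aware logistic background mutation model (reference base class,
    replication timing, coverage, per-tumour load), tests each region for
    mutational recurrence with an exact Poisson-binomial tail combined with a
    positional-clustering permutation test, and links recurrently mutated
    regions to expression change with a conditional negative-binomial
    two-group test. Also provides focal copy-number and karyotype calling,
    mutational-signature refitting against a 96-channel catalog, AID-motif
    classification, and cohort contingency statistics, together with a fully
    seeded synthetic-cohort generator with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    withr,
    jsonlite,
    stats,
    utils,
    methods,
    IRanges,
    S4Vectors,
    Biostrings,
    edgeR,
    pracma
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
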