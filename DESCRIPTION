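Package: manoscreen
Title: Analysis of Pooled Barcode Competition Screens (MANO Method)
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A complete analysis pipeline for mixed-all-nominated-in-one
    (MANO) pooled barcode competition screens used to annotate the
    transforming activity and kinase-inhibitor sensitivity of gene
    variants. Provides amplicon barcode extraction and counting from
    FASTQ reads, growth and drug normalization of clone count matrices,
    a Bayesian ordered-regression random-effects model that integrates
    ordinal transformation-assay scores into a transformation activity
    score (TAS), a five-class oncogenicity classifier, three-parameter
    log-logistic dose-response fitting with IC50 comparison, UPGMA
    clustering of drug-sensitivity profiles, and a synthetic-data
    generator with known ground truth for closed-loop validation.
License: MIT
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
    jsonlite,
    rjags,
    coda,
    minpack.lm,
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
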