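Package: spliceimpact
Title: Functional Impact Annotation of Differential Alternative Splicing Events
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotates differentially alternatively spliced (DAS) exons for
    their impact on protein sequence and annotated functional domains.
    Given transcript models, a genome, and a table of DAS events, the
    package constructs the inclusion/exclusion isoform pair for each
    event, translates both isoforms, quantifies the amino-acid difference,
    lifts protein-domain coordinates across the pair to classify each
    domain as intact, internally altered, truncated or lost, filters
    events whose changed-domain descriptions share non-stopword tokens
    with the gene's GO term names, and ranks pathways over the filtered
    gene list with a one-sided Fisher's exact test. A deterministic
    synthetic-fixture generator plants events with machine-readable truth
    labels so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    methods,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    tibble,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
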