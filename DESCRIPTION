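Package: crhub
Title: Cis-Regulatory Hubs from Activity-by-Contact Enhancer-Promoter Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds cis-regulatory hubs (CRHs) from binned chromatin-contact
    matrices and epigenomic peak tracks. Scores candidate distal element to
    promoter links with the activity-by-contact (ABC) model, thresholds them
    into functional pairs, assembles CRHs as connected components of the
    resulting bipartite graph, characterises hub topology and overlap with
    A/B compartments, TADs, FIREs and chromatin states, and runs the
    disease-enrichment statistics used to relate hubs to GWAS variants,
    associated genes, expression and differential expression. Ships a seeded
    synthetic-data generator with planted hub structure so the whole pipeline
    is testable end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    igraph,
    IRanges,
    S4Vectors,
    jsonlite,
    generics,
    mclust,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    lme4,
    withr
Config/testthat/edition: 3
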