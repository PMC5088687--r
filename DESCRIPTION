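Package: loop4c
Title: 4C-Seq Viewpoint Interaction Analysis with Network and Hi-C Integration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrative pipeline for circular chromosome conformation
    capture (4C-seq) viewpoint analysis: in-silico restriction digestion into a
    virtual fragment library, read-to-fragment assignment with viewpoint
    filtering, profile normalization, smoothing and distance-decay correction,
    multi-scale domainogram calling of significantly interacting regions
    (BRICKs) with permutation-based false discovery rate tiers, interval
    annotation and window/cytoband enrichment, a network K-function
    (Knet) connectivity test for gene hit sets, differential-expression
    criteria with chromosome-distribution bias testing, and Hi-C matrix
    balancing, observed/expected transformation, coarsening and virtual-4C
    cross-validation. A synthetic-data module generates every input the
    pipeline consumes with the statistical structure the analysis assumes.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    generics,
    igraph,
    Biostrings,
    jsonlite,
    yaml,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
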