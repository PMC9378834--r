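Package: reopairs
Title: Rank-Based Single-Sample miRNA Pair Classifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Construction and application of single-sample diagnostic
    classifiers built from within-sample relative expression orderings
    (REOs) of miRNA pairs. Mines miRNA pairs whose ordering is stable
    across a control cohort, screens for pairs whose ordering is
    significantly reversed in cancer samples (one-sided Fisher's exact
    test with Benjamini-Hochberg correction), assembles a minimal
    majority-voting pair panel by greedy coverage search, frequency
    ranking and the sqrt(PPV x NPV) evaluation index, and applies the
    resulting panel to individual samples with no cross-sample
    normalisation. Includes readers for plain TSV and GEO series-matrix
    expression tables, published 13-pair and 17-pair serum panels for
    ovarian cancer, a linear 10-miRNA comparator model, diagnostic
    performance metrics, and a seeded cohort simulator with planted
    reversed pairs for end-to-end validation.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
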