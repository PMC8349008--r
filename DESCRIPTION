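Package: psnet
Title: Patient-Sharing Provider Networks from Mental-Health Claims
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds and characterizes patient-sharing networks of healthcare
    providers from administrative claims for adults with mental illness.
    Includes cohort construction (age, diagnosis-hierarchy and provider-type
    filters), thresholded projection of patient-provider claims into an
    undirected provider graph, fast-greedy modularity community detection
    applied hierarchically to yield communities and nested sub-communities,
    per-patient Bice-Boxerman continuity-of-care and per-provider structural
    metrics (degree, local transitivity, alter continuity), sub-community
    summaries with size correlations, and community random-intercept linear
    mixed models relating transitivity to continuity of care. A
    synthetic-claims generator with planted hierarchical community structure
    makes every stage testable without restricted claims data.
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
    stringr,
    igraph,
    lme4,
    generics,
    ggplot2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
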