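Package: sigflux
Title: Constraint-Based Modeling and Transcriptomic Contextualization of
    Stoichiometric Signaling Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for constraint-based modeling (COBRA) of stoichiometric
    signaling networks, centred on Toll-like-receptor-style cascades.
    Provides a tabular model dialect with Boolean gene-reaction
    associations, flux balance analysis, parsimonious (L1 minimum-norm)
    flux balance analysis, flux variability analysis and energy robustness
    scans on a self-contained linear-programming core, structural network
    diagnostics (dead-end compounds, blocked reactions, connectivity),
    transcriptomics-driven model tailoring from presence/absence calls,
    fold-change-driven flux bound adjustment, input/output-relationship
    simulation harnesses, gene-set sub-network extraction, and synthetic
    network and expression-data generators with recorded ground truth.
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
    purrr,
    readr,
    rlang,
    tibble,
    tidyr,
    xml2
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
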