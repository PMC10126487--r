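Package: facilinet
Title: Facilitative Interaction Networks from Microbial Community Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying facilitative (cross-feeding) interaction
    networks through microbial community time series. Provides a windowed
    abruptness index for detecting rapid compositional shifts (Bray-Curtis
    dissimilarity between adjacent time windows), a set-based cross-feeding
    model yielding directional species coupling scores, metabolite transfer
    attribution, metabolic interaction potential and metabolic resource
    overlap, directed dependency-network construction with feedback-loop
    edge classification, hierarchy metrics on the strongly-connected-component
    condensation (treeness, feedforwardness, orderability), and keystone-taxon
    ranking by influence (reaching) and PageRank centrality. Includes seeded
    synthetic-data generators for abundance series with planted regime shifts
    and toy metabolic communities with planted dependency loops, so the whole
    pipeline is testable without external data.
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
    tibble,
    tidyr,
    tools,
    utils,
    vegan,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
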