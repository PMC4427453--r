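Package: transnet
Title: Inter-Chromosomal Hi-C Contact Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Statistical analysis of inter-chromosomal (trans) Hi-C
    contacts at fixed-size genomic segments. Calls significant segment
    contacts with a binomial model against a supplied background
    probability matrix, applies Benjamini-Hochberg false discovery rate
    control with a chromosome-length normalization, builds segment and
    gene interaction networks, generates matched geometric random
    networks rewired toward the observed transitivity, summarizes
    network topology, quantifies genomic-feature enrichment of
    trans-interacting segments, tests rank-binned association between
    spatial proximity and gene co-expression or functional similarity,
    and scores cross-species contact conservation over synteny regions.
    Includes a synthetic-data generator that plants known contacts,
    hubs, feature enrichment, co-expression structure and conserved
    contacts so the whole pipeline can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
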