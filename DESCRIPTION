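Package: deepbioreg
Title: Deep-Sea Bioregionalization from Benthic Occurrence Records
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for delimiting deep-sea biogeographical units
    from benthic occurrence records. Curates Darwin-Core-style occurrence
    tables (study-area, depth-window and species-rank filters, local synonym
    mapping), assigns records to alternative biogeographical classification
    schemes built from latitude bands and depth strata (depth-province,
    hybrid ecoregion-by-depth, and water-mass-by-region schemes for the
    Brazilian continental margin, plus a consolidated proposal), computes
    Simpson turnover dissimilarity between unit assemblages, and resolves the
    tie-prone dissimilarity structure with order-randomized UPGMA consensus
    dendrograms, species-resampling bootstrap node support, multiscale
    bootstrap support profiles and trend-based node classification. Includes
    a synthetic assemblage generator with known planted structure so every
    stage is testable without external data downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
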