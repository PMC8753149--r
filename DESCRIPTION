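Package: connectiscape
Title: Graph-Theoretic Habitat Connectivity and Conservation Scenario Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A species-specific pipeline from occurrence records and gridded
    environmental layers to conservation priorities: spatial thinning and
    correlated-predictor pruning, a climate-envelope suitability model with
    minimum-training-presence thresholding and elevation clipping, delineation
    of suitable habitat patches (cover classes, home-range size filter, forest
    loss update), species-specific resistance surfaces and least-cost patch
    graphs bounded by allometric dispersal distances, patch-importance indices
    (betweenness centrality, dIIC via the integral index of connectivity, and
    quality-weighted area), rank-based selection of connectivity areas up to a
    habitat target, and area-matched comparison of protected-area versus
    payment-for-ecosystem-services conservation scenarios. Includes a synthetic
    landscape generator so the whole pipeline is testable without geodata
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
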