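Package: braintopo
Title: Topology of Brain Morphological Similarity and Functional
    Connectivity Networks Across Spatial and Temporal Scales
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds individual morphological similarity networks (histogram
    correlation of vertex-wise cortical volume, area and thickness over a
    sweep of bin numbers) and static plus sliding-window dynamic functional
    connectivity networks on a cortical parcellation, thresholds them with
    orthogonal minimal spanning trees (OMST) selected by global cost
    efficiency, computes seven weighted-graph topological measures (global,
    nodal and local efficiency; degree, betweenness, eigenvector and
    pagerank centrality), summarizes their variation across spatial scales
    and temporal windows (coefficient of variation, histogram and
    kernel-density distribution statistics), and relates them to behavioral
    scores through covariate-adjusted partial correlation with
    Benjamini-Hochberg false discovery rate control. Includes a synthetic
    cohort generator (behavior, morphometry, band-limited BOLD) so the full
    pipeline is testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    MASS,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
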