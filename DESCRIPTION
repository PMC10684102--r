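Package: ltcov
Title: Laminar Thickness Covariance Analysis of the Cortical Sheet
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Surface-based analysis of laminar (cortical layer) thickness
    covariance. Builds parcel-by-parcel covariance matrices from per-vertex
    6-layer thickness maps (partial correlation against the cortex-average
    profile, Fisher z-transformed), embeds them into principal axes via a
    normalized-angle affinity kernel, relates the axes to directed-connectivity
    hierarchy and to distance-dependent models of structural and functional
    connectivity, and provides spatially constrained null models
    (spin permutations and variogram-matched surrogates) for inference.
    Includes a seed-deterministic synthetic-cortex generator (icosphere
    meshes, spatially autocorrelated layer fields with a planted axis,
    directed connectivity with planted hierarchy) so that every stage of the
    pipeline is testable without external atlas downloads, plus GIFTI and CSV
    readers and writers for real surface data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    igraph,
    Matrix,
    minpack.lm,
    jsonlite,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
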