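Package: amwave
Title: Travelling-Wave Growth and Network Analysis of Arbuscular Mycorrhizal Colonies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for time-resolved spatial network graphs of
    arbuscular mycorrhizal fungal colonies. Implements a branching-annihilating
    range-expansion (BARE) travelling-wave model with an optional
    diffusion-limited phosphorus absorption extension, equal-area ring-frame
    density estimation with bootstrap uncertainties and sigmoid arrival-time
    fits, tracking-based detection of branching, anastomosis and crossing
    events with rate-scaling estimation of the branching and annihilation
    coefficients, root-anchored betweenness centrality and transport
    efficiencies normalized to minimum-spanning-tree and Delaunay reference
    networks, and kymograph-based bidirectional flow velocimetry. An
    agent-based colony simulator generates synthetic networks with ground
    truth for validating every estimator end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    deldir,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
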