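Package: oxsens
Title: Oxidation Sensitivity Scoring of Joint Proteomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for nominating oxidation-sensitive key proteins
    in a joint (cartilage) proteome. Quantifies per-site oxidative
    post-translational modification changes as percent change per modified
    site, computes protein-protein interaction network eigenvector centrality
    calibrated to the whole-proteome scale, partitions the detected subnetwork
    with Louvain community detection, evaluates an electrostatic
    (Debye-Hueckel screened Coulomb, Flory polymer scaling) model of
    oxidation-induced folding destabilization, and integrates centrality and
    destabilization susceptibility into a min-max normalized composite
    sensitivity score (CSS) that ranks proteins by predicted proteome
    perturbation impact. Includes a synthetic-data module that emulates
    proteomes with controlled charge composition, scale-free interaction
    networks with planted hubs, and site-level PTM evidence with planted
    effects, so the full chain is testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    MASS,
    methods,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
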