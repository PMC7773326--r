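Package: chromodamage
Title: Chromosome Conformation Inference and Radiation-Induced DNA Damage
    Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers 3D genome conformations from Hi-C-derived TAD contact
    constraints with a Markov-chain Monte Carlo polymer model (gtrack input,
    sphere or ellipsoid nuclei, lamina-associated-domain constraints, CMM
    export), couples the solved geometries to a radiation DNA damage model
    (energy-deposition classification, DSB/SSB clustering, photon and
    LET-scaled track exposures, SDD output), and provides spatial damage
    statistics: inter/intra-chromosomal clustering with a homolog rule,
    edge-corrected 3D Ripley-K, radial positioning, chord adjacency, and
    Kolmogorov-Smirnov/Benjamini-Hochberg significance grids.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    xml2
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
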