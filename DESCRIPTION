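Package: evacsim
Title: Agent-Based Tsunami Evacuation Simulation with Coupled Attitude Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for studying how urban structure shapes
    pedestrian tsunami evacuation. Generates synthetic grid-like (coastal
    plain) and root-like (ria-valley) urban models, builds least-cost
    navigation fields over land-use rasters, and couples bounded-confidence
    evacuation-attitude dynamics over a radius-limited directed communication
    graph with social-force pedestrian movement. Includes stochastic ensemble
    experiments (resampled initial attitudes or leading-evacuee assignments),
    strongly-connected-component cluster analysis of the communication
    networks, and evacuation metrics such as completion ratios, large-group
    composition and behaviour-change ratios.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    ggplot2,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
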