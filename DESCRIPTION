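Package: pllpsim
Title: Mechanics-Based Simulation of Rosette Dynamics in the Migrating
    Lateral Line Primordium
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Two tissue-mechanics simulators of the migrating zebrafish
    posterior lateral line primordium: a spring-linked agent-based model of
    cell clustering under differential leading/trailing migration, and a
    two-dimensional Cellular Potts (Glazier-Graner-Hogeweg) model with
    compartmentalized epithelial cells and breakable focal-point-plasticity
    spring links. Includes rosette/cluster detection, kinematic readouts,
    scenario presets (wild-type migration, leading-cell stalling and
    recovery, elevated lateral contractility), and a reproducible runner
    with YAML configuration.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    yaml,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
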