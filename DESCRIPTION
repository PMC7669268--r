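Package: ctlswarm
Title: Agent-Based Simulation and Quantification of Cytotoxic T-Cell
    Swarming Around Tumouroids
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates cytotoxic T lymphocyte (CTL) swarming around a central
    tumouroid in a cylindrical well: agents re-enact bootstrapped 10-minute
    blocks of motility, sense a homotypic chemokine signal resolved by
    heat-kernel superposition over secretion events, and switch between
    undirected, chemotactic and intratumoural behaviour according to
    per-agent log-normal sensing thresholds. Ships the quantification
    suite used for whole-well imaging of such assays (swarming index,
    forward migration index, infiltration statistics, radial density
    kymographs, transmigration and cytotoxicity indices), a synthetic
    3D persistent-random-walk track generator so every component is testable
    without imaging data, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
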