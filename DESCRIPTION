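Package: sggsim
Title: Agent-Based Simulation of Self-Generated Chemoattractant Gradients
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Couples a diffusing, degradable attractant field (DuFort-Frankel
    finite differences) to motile cell agents with saturable receptors,
    Michaelis-Menten attractant degradation (optionally induced by receptor
    occupancy through a Hill function), a persistent biased random walk, and
    attractant-driven mitosis. Provides declarative builders and scoring
    statistics for four in-silico chemotaxis assays (bridge, population scan,
    radial disc-well, two-spot) used to study the robustness of chemotaxis to
    self-generated versus imposed attractant gradients.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    tibble,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    optparse
Config/testthat/edition: 3
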