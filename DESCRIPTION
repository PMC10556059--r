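Package: sargasso
Title: Tissue Stoichiometry and Surface Drift Backtracking for Pelagic Sargassum
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing the elemental composition of pelagic Sargassum
    and the surface transport history of floating material. Implements the
    Michaelis-Menten model of coupled arsenate/phosphate uptake and its
    prediction that tissue As:P varies hyperbolically with phosphorus content,
    log-log power-law fitting with bootstrap inference and spurious-ratio null
    models, two-end-member nitrogen isotope mixing, and Lagrangian particle
    tracking (forward or backward) in gridded surface currents with windage and
    random-walk horizontal diffusion. A synthetic-data module generates tissue
    tables with known power-law structure and analytic velocity fields with
    closed-form trajectories so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
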