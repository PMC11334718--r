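Package: cntkchan
Title: Biomimetic Carbon-Nanotube Potassium Channel: Model Construction
    and Trajectory Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds atomistic models of carbonyl-decorated armchair carbon
    nanotube channels that mimic the KcsA potassium-channel selectivity
    filter, and analyses ion-permeation trajectories through them:
    permeation-event detection and knock-on/mode classification, cumulative
    fluxes and K+/Na+ selectivity ratios, radial distribution functions,
    coordination and hydration-shell statistics, spatial densities, smeared
    Coulomb electrostatic-potential profiles, and reconstruction of
    potentials of mean force from umbrella-sampling windows via the
    weighted histogram analysis method (WHAM).  A synthetic-data module
    generates stochastic hopping trajectories, biased umbrella samples and
    solvation snapshots with known ground truth so that every analysis
    stage is testable without molecular dynamics.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    jsonlite,
    yaml,
    rlang,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
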