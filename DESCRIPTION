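Package: poremech
Title: Membrane Pore Energetics from Free-Energy Profiles and Continuum Elasticity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the mechanical stability of lipid membranes against
    transmembrane pore formation. Implements the joint pore
    nucleation/expansion reaction coordinate on annotated particle
    configurations, extraction of nucleation free energies and rim line
    tensions from one-dimensional potentials of mean force,
    Helfrich-Kozlov-Hamm continuum pore energetics with a closed-form rim
    line tension, fluctuation-based estimators of tilt and bending moduli and
    of spontaneous curvature from lateral stress profiles, area-rescaled pore
    probabilities, and cylindrical lipid density maps that quantify lateral
    sorting at the pore rim. A synthetic-data generator with known ground
    truth stands in for molecular-dynamics trajectories so every stage is
    testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    graphics,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
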