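Package: scco2sol
Title: Density-Based Solubility Correlation of Solid Drugs in Supercritical CO2
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Correlates isothermal solid-solute solubility data in supercritical
    carbon dioxide with eight density-based models: a solid-liquid-equilibrium /
    regular-solution model with an infinite-dilution activity coefficient, the
    Alwi-Garlapati, Sodeifian and Reddy-Garlapati correlations, and the classical
    Chrastil, reformulated Chrastil, Bartle and Mendez-Santiago-Teja (MT) models.
    Parameters are estimated by deterministic multi-start nonlinear regression
    (Latin-hypercube starts, bounded Levenberg-Marquardt pass, Nelder-Mead
    polish), fits are compared by AARD%, R-squared and the corrected Akaike
    information criterion, and vaporization, total and solvation enthalpies are
    derived from the fitted 1/T slopes. Ships a 24-point pantoprazole sodium
    sesquihydrate dataset (308-338 K, 12-27 MPa), a synthetic-data generator for
    parameter-recovery studies, crossover-pressure detection and the MT
    self-consistency transform.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    lhs,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
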