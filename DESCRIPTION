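Package: actipath
Title: Activity-Based Thermodynamic Feasibility Analysis of Metabolic Pathways
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts metabolite activity coefficients in aqueous salt and buffer
    media with an electrolyte PC-SAFT equation of state (hard-chain, dispersion,
    Wertheim association and Debye-Hueckel contributions), converts measured
    equilibrium-concentration ratios of biochemical reactions into thermodynamic
    equilibrium constants and standard Gibbs energies (pH speciation transforms and
    van 't Hoff temperature corrections included), and runs activity-based
    thermodynamic feasibility analyses of glycolysis or arbitrary reaction lists
    under user-defined cytosolic conditions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
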