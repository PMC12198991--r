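Package: gavthermo
Title: Benson Group-Additivity Gas-Phase Thermochemistry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimation of gas-phase absolute entropy, entropy of formation
    and Gibbs energy of formation for C/H/N/O organic molecules by Benson
    group additivity, using a multiple-linear-regression-derived group-value
    table for carboxylic acids and cyclic imides.  Includes Hess's-law and
    Gibbs-relation algebra, functional-group perception from molecular
    graphs or SMILES, refitting of group values by ordinary least squares
    with holdout evaluation, cubic heat-capacity polynomials, reaction
    thermochemistry and equilibrium constants, and a synthetic-data
    generator for pipeline validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    MASS,
    stats,
    utils
Suggests:
    ChemmineOB,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
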