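Package: satsol
Title: Saturation Solubility-pH Speciation with Aggregation and Salting Corrections
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Mass-action analysis of saturation solubility-pH profiles of
    sparingly soluble ionizable compounds. Implements a forward speciation
    engine for a diprotic acid that self-associates into a neutral dimer and
    precipitates as the free acid or sodium salts, ionic-strength corrections
    of charged-species constants by a Stokes-Robinson hydration scheme,
    Setschenow and self-interaction salting corrections for neutral species,
    weighted nonlinear least-squares refinement of equilibrium constants
    (including block-diagonalization for strongly correlated parameters and
    electrode junction-potential standardization), Setschenow line fits and
    Abraham linear free-energy prediction of salting-out constants, and a
    seeded synthetic-data generator emulating classical solubility-pH
    titration designs so the whole pipeline is testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    minpack.lm,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
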