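Package: broilerNE
Title: Net Energy Determination and Prediction for Broiler Feed Ingredients
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Energy-balance computation for broiler feeding trials combining
    total excreta collection and open-circuit indirect calorimetry: apparent
    metabolizable energy (AME, AMEn) from total collection, heat production
    and respiratory quotient from gas exchange, partition of AME intake into
    heat increment and retained energy, and diet-level net energy (NE).
    Ingredient AME/AMEn/NE by the reference-diet substitution method,
    stepwise multiple-regression prediction equations for ingredient NE with
    a pairwise-collinearity screen, Duncan's multiple-range grouping, and a
    synthetic feeding-trial generator with ground truth for end-to-end
    parameter-recovery testing. Ships the proximate compositions, diet
    formulations and measured energy values of a 5-wheat / 5-wheat-bran
    broiler trial as plain-text fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
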