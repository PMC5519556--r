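Package: qstracr
Title: Mechanism-Based Acute-to-Chronic Toxicity Extrapolation for
    Luminescent Bacteria
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative structure-toxicity relationship (QSTR) tools for
    extrapolating the chronic (24 h) toxicity of antibiotics on the
    luminescent bacterium Vibrio fischeri from acute (15 min)
    bioluminescence-inhibition data and protein-ligand interaction-energy
    descriptors. Implements linear log-dose dose-response fitting and EC50
    algebra, toxic-unit analysis of equitoxic binary mixtures, regressions of
    the chronic/acute slope ratio on docking-based energies, internal
    (LOO/LTO/LMO Q2) and external (Q2F1, RMSEP) validation, Williams-plot
    applicability-domain diagnostics, symbolic composition of the fitted
    sub-models into closed-form extrapolation equations, and a seedable
    synthetic-data generator with the same statistical structure as the assay
    data. Ships a reference panel of 15 antibiotics (sulfonamides, sulfonamide
    potentiators, tetracyclines).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
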