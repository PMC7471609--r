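Package: fluxkit
Title: Constraint-Based Flux Simulation and Multi-Omics Integration for
    Genome-Scale Metabolic Models of Fermentative Anaerobes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Author: Package Author [aut, cre]
Maintainer: Package Author <author@example.org>
Description: Tools for condition-specific simulation of genome-scale
    metabolic models of fermentative anaerobes: flux balance analysis,
    parsimonious flux balance analysis by quadratic norm minimization,
    loopless flux variability analysis, gene-protein-reaction knockout
    logic, blocked-reaction detection, and mass/charge balance checking.
    Includes training of growth- and non-growth-associated ATP
    maintenance parameters from measured extracellular fluxes, a
    fold-change-based protocol for integrating gene-level omics data
    with simulated fluxes, mutant lethality and medium-supplement rescue
    screening, and deterministic synthetic fixture generators (toy redox
    core models, maintenance flux datasets, planted omics datasets).
    Models are read and written as SBML Level 3 with the FBC version 2
    extension.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    MASS,
    xml2,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    quadprog,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
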