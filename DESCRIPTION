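Package: pdoflux
Title: Constraint-Based Phenotype Prediction for 1,3-Propanediol-Producing Anaerobes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting steady-state flux phenotypes of anaerobic,
    glycerol-fermenting bacteria from genome-scale metabolic models. Implements
    flux balance analysis under a linear biomass objective and under two
    non-linear objectives (biomass yield per squared enzyme usage, and a
    weighted variant that additionally penalizes ATP production), an allosteric
    logistic upper bound on acetate secretion, flux variability analysis with a
    relaxed (possibly non-linear) objective, regulatory on/off minimization
    (ROOM) knockout prediction, flux-coupling classification of reactions and
    enzymes relative to growth, blocked-metabolite detection, qualitative
    proteome/transcriptome consistency scoring, biomass-composition
    perturbation screens, and glucose-glycerol co-fermentation yield surfaces.
    Includes SBML and tabular model input/output and synthetic fixture
    generators for a small anaerobic glycerol network.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    nloptr,
    purrr,
    quadprog,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
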