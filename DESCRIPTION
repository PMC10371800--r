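Package: fluxmpc
Title: Flux-Target Model Predictive Control of Fed-Batch CHO Bioreactors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multiscale control framework for fed-batch Chinese Hamster Ovary
    (CHO) cell cultures. Stage-wise flux balance analysis on a stoichiometric
    metabolic network produces optimal target exchange fluxes for five culture
    phases; a Monod-kinetic digital twin of the reactor simulates cell growth,
    nutrient uptake, metabolite secretion and antibody production under
    piecewise-linear feeding policies; and a receding-horizon model predictive
    controller computes feeding strategies that minimise the integrated squared
    deviation of realised specific fluxes from the stage targets. Includes a
    self-contained toy fixture bundle (reduced metabolic network, nominal
    kinetics, baseline feed), CSV/TSV/SBML/YAML interfaces and a command-line
    entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    nloptr,
    quadprog,
    stats,
    tools,
    utils,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
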