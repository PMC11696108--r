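Package: hostfactory
Title: Host-Aware Design of Microbial Cell Factories for Batch Production
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Mechanistic design of engineered bacteria for chemical
    production from batch cultures. Implements a host-aware single-cell
    model in which heterologous enzyme expression competes with native
    genes for ribosomes and translation precursor, embeds it in a
    batch-culture simulator (biomass, substrate, product, inducer), and
    searches enzyme transcription scalings and inducible genetic-circuit
    designs (topology, control strengths, induction time) with an elitist
    multiobjective genetic algorithm to maximise volumetric productivity
    and product yield. Includes Pareto-front utilities (nondominated
    filtering, hypervolume, knee-point selection), a convex-hull robustness
    measure under parameter perturbation, and reproducible experiment
    drivers with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    grDevices,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
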