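Package: seepaom
Title: Reaction-Transport Modelling and Methane Budgets for Cold-Seep
    Sediments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying anaerobic oxidation of methane (AOM) in
    marine cold-seep sediments from depth-resolved porewater and solid-phase
    profiles. Implements a one-dimensional steady-state reaction-transport
    model of sulfate- and iron-driven AOM (six dissolved species, two solid
    iron phases), Fick's-law diffusive flux estimation with stoichiometric
    conversion to manganese-driven AOM, geochemical zonation of sediment
    cores, depth-integrated rate budgets partitioned among sulfate-, iron-
    and manganese-coupled pathways, parameter calibration, sedimentation-rate
    sensitivity analysis, and Spearman correlation matrices with exact
    permutation p-values. Includes a synthetic-profile generator that
    emulates a seep piston core for end-to-end testing and parameter-recovery
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
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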