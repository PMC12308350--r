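Package: avidity
Title: Bivalent Antibody-Antigen Binding Kinetics, Equilibria and Avidity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mechanistic mass-action model of a bivalent, monospecific IgG
    antibody binding mobile antigens on a target cell membrane. Provides the
    full and reduced kinetic ODE systems and their numerical integration to
    steady state, a semi-analytic equilibrium via the scaled cubic with
    guaranteed selection of the unique positive root, equilibrium binding-state
    metrics (antigen occupancy, bound-antibody ratios), dose-response sweeps
    with EC50 extraction and the avidity shift (delta EC50) between bivalent
    and monovalent antibodies, and variance-based (Sobol) global sensitivity
    analysis with Saltelli quasi-random sampling and a dummy-parameter control.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
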