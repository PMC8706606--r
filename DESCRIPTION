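Package: cfrsim
Title: Cyclical Fate Restriction Gene-Network Simulator
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic simulation and analysis of generalized repressilator
    gene-regulatory networks used to model cyclical fate restriction in
    multipotent progenitor cells. Builds mutual-repression network models with
    OR or AND repression logic, integrates their dynamics under constant or
    ramped global coupling, classifies trajectories into multipotent,
    oscillatory, and differentiated regimes, locates regime boundaries by
    equilibrium and linear-stability analysis, and runs in-silico experiments:
    coupling-ramp fate-choice ensembles, fate-specific signal-driven exit from
    the oscillatory regime, gene knockouts, and network-topology scans.
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
    arrow,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
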