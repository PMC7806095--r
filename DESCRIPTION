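Package: anttower
Title: Agent-Based Simulation and Analysis of Fire Ant Tower Building
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Discrete-time lattice agent-based model of collective tower
    building in fire ants (Solenopsis invicta).  Simulates free, locked and
    covered agents on a periodic L x L x infinity cubic lattice with
    neighbor-influenced locking, spontaneous unlocking, and local attraction;
    reduces configurations to per-tower geometry via wrap-aware connected
    components of the height map (agent count, maximum height, equivalent
    diameter, aspect ratio); provides parameter sweeps with phase-transition
    onset detection, tower-trajectory tracking with mean-squared-displacement
    diffusion estimation, and CMA-ES optimization of tower size and height.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, Rcpp, jsonlite
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), igraph
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'RcppExports.R'
    'anttower-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'params.R'
    'world.R'
    'rules.R'
    'simulate.R'
    'metrics.R'
    'dynamics.R'
    'optimize.R'
    'io.R'
    'cli.R'
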