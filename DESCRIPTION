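Package: cellmotion
Title: Off-Lattice Agent-Based Simulation of Collective Cell Migration in 3D
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the three-dimensional migration of groups of cells through
    extracellular matrix with an off-lattice, cell-center agent-based model.
    Cells are spheres carrying coarse-grained surface receptor sites: cell-cell
    adhesion sites engage one-to-one across neighboring cells, cell-matrix sites
    generate radially outward traction when exposed to the matrix, and soft-sphere
    repulsion with an incompressible core limits overlap. Motion is overdamped
    (Stokes drag) and integrated with a fixed-step fourth-order Runge-Kutta scheme
    whose stochastic site configuration is frozen within each step. Includes pair
    stability experiments (time of first break-up, companion time, break-up
    fractions with Gompertz fits), adhesion-depletion schedules, and cluster
    dissociation analyses (radius of gyration, overlapping-neighbor counts).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
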