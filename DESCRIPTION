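Package: AirwaySpectra
Title: Spectral Analysis of Resistive Airway Tree Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models gas flow in lung airway networks as linear resistive
    trees and analyses them through two linear operators: the conductance
    Laplacian and the Maury matrix, a dense symmetric operator on the
    terminal (acinar) nodes whose entries are shared-path resistances.
    Provides tree construction from edge lists, asymmetric Weibel and
    Horsfield-order tree generators, random airway constrictions, sparse
    direct and modal flow solves under pressure boundary conditions, a
    compliance-driven tidal ventilation model with a closed-form periodic
    solution, and reduced-order estimation of ventilation heterogeneity
    from the largest-eigenvalue Maury modes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    igraph,
    deSolve,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
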