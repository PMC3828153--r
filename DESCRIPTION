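Package: proteoPath
Title: Transition-Path Analysis of Chaperone-Mediated Proteostasis Kinetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Kinetic modelling of a reduced Escherichia coli proteostasis network
    (client protein folding, misfolding and aggregation coupled to the DnaK/DnaJ/GrpE,
    GroEL/GroES and ClpB+KJE chaperone systems, Lon degradation and re-synthesis)
    together with a transition-path analysis of the resulting dynamics. The bulk
    mass-action system is integrated with a stiff solver, a single-tagged-molecule
    rate matrix is extracted by freezing bulk concentrations at an analysis time,
    and committor probabilities, conditional committors, mediation probabilities
    and entry-channel pathway decompositions quantify which chaperone system
    carries misfolded-to-unfolded and unfolded-to-native transitions. Includes
    scripted experiment sweeps (synthesis rate, chaperone binding factor, GroELS
    capacity), a continuous-time stochastic path sampler for validation, and
    plain-text import/export of models, matrices and results.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    tools,
    utils,
    deSolve,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
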