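Package: mutantgraph
Title: Hierarchical Management and Simulation of Model Parameterizations
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Manage large collections of parameterizations ("mutants") of a
    single SBML biochemical reaction model as directed acyclic graphs with
    value inheritance. Nodes override a small number of values locally, either
    numerically or with algebraic expressions referencing ancestor nodes
    (parameter@node); multi-parent nodes inherit the union of their parents'
    changes, with automatic detection and explicit resolution of conflicting
    redefinitions. Separate inheritance graphs configure time-course
    simulation settings and plot settings, each applicable to declared subsets
    of mutants. Any consistent configuration can be simulated deterministically
    with a built-in adaptive stiff ODE integrator, exported as a flattened
    SBML Level 3 Version 1 file, rendered to Graphviz DOT, or written as CSV
    time series; whole projects persist to a documented JSON format. A
    command-line interface exposes the full workflow for scripting.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    xml2,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
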