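Package: nemodyn
Title: Connectome-Constrained Neural Network Dynamics and Bifurcation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Single-compartment membrane-voltage dynamics on a connectome with
    ohmic gap junctions and graded chemical synapses, in the style of full
    network models of C. elegans neural activity. Provides construction of
    the standard equilibrium and per-neuron sigmoid thresholds, analytic
    Jacobians and linear stability, Newton continuation of fixed-point
    branches over an input-amplitude grid, stiff time integration,
    classification of trajectory tails into fixed points and limit cycles, a
    two-mode motorneuron projection plane obtained by singular value
    decomposition, ensemble bifurcation diagrams, basin-of-attraction maps on
    the projection plane, and transient convergence-time measurement.
    Includes a synthetic-connectome generator and deterministic test fixtures
    so every stage is testable without external connectivity data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
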