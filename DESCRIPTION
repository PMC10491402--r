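Package: motifid
Title: Structural Identifiability Analysis of Biomolecular Controller Motifs
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Constructs the library of basic and antithetic homeostatic
    controller-motif ODE models, includes concentration and/or flow
    measurements as model outputs (either by augmenting flows as states or by
    placing flow expressions directly in the output), and decides local
    structural identifiability and observability from the generic rank of the
    observability-identifiability matrix built from successive Lie derivatives
    of the outputs. Ranks are evaluated at generic points either exactly over
    a prime field or numerically with randomized draws, with the standard
    early-stopping rules. Includes per-element identifiability diagnosis,
    verification of Lie symmetry generators, sweep drivers that classify and
    score measurement combinations across the whole motif library, a plain-text
    model grammar for user-defined rational ODE models, and a command-line
    interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), deSolve, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
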