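Package: evofit
Title: Evolutionary Fitness and Ranking of Inherited Strategies in
    Self-Replicating Systems
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for modelling natural selection in deterministic
    self-replicating systems with strong inheritance.  Simulates density
    dynamics over a discretised compact strategy space (replicator systems
    and nonlocal logistic competition), establishes pairwise ranking orders
    between strategies from the long-term behaviour of density ratios, and
    computes evolutionary fitness both empirically (long-term average
    per-capita growth rate of a generalised density) and analytically for
    stage-structured population models (dominant eigenvalue of the
    life-history matrix divided by the limitation sensitivity) and for
    delay models (rightmost root of the transcendental characteristic
    equation divided by the limitation sensitivity), including the
    reduction of von Foerster age-structured populations to delay systems.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
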