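Package: aropt
Title: Acceptance-Ratio Driven Simulated Annealing and Replica Exchange
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: General-purpose Monte Carlo optimization engine in which the
    annealed (or replica-exchanged) quantity is the target acceptance ratio
    rather than the temperature: a feedback controller adapts an unconstrained
    pseudo-temperature so that the observed per-window acceptance ratio tracks
    a prescribed target. Any modelling problem plugs in through three user
    callbacks (move rule, model, evaluation) operating on an opaque parameter
    state. Provides acceptance-ratio simulated annealing with seed fan-out for
    parallel runs, acceptance-ratio replica exchange with unconditional
    configuration swaps between fixed-acceptance-ratio replicas, deterministic
    seeded trace tables, plain-text configuration files, and self-contained
    example problems (polynomial coefficient fitting, two-compartment kinetic
    ODE parameter estimation, and lock-constrained combinatorial shuffling).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    parallel,
    stats,
    utils,
    yaml
Suggests:
    e1071,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
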