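Package: corneasim
Title: Stochastic Lattice Simulation of Corneal Epithelium Homeostasis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Agent-based lattice Monte-Carlo simulation of clonal dynamics in
    the basal layer of the corneal epithelium. Limbal stem cells at the tissue
    circumference feed a disk of progenitor cells with finite replicative
    lifespan; replication and removal events may be spatially coupled (removal
    drawn from a local neighbourhood of the dividing cell) or uncoupled, with
    tunable centripetal bias, under either an equipotent or a hierarchical
    limbal stem-cell model. The package provides the event-driven simulator,
    clonal pattern statistics (renewed fraction, front depth, clonal unmixing,
    post-mitotic profiles, clone counts and size distributions), closed-form
    renewal-time benchmarks, deterministic pattern fixtures, and a command-line
    interface for reproducible runs and parameter sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
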