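Package: fuzzlink
Title: Data-Derived Fuzzy-Logic Modeling of Signaling Network Plasticity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Trains parameter-reduced first-order Takagi-Sugeno fuzzy models
    (gFIS) of signaling intermediates from perturbation time-course
    phosphoproteomics data, assembles per-condition fits into multi-treatment
    models (mtFIS), simulates them synchronously over a prior-knowledge
    network, and retrains over truncated time windows to separate static
    topology mismatches from time-defined signaling rearrangements. Includes a
    penalized root-mean-square training objective with multi-start
    derivative-free optimization, bootstrap sensitivity analysis,
    leave-one-out cross-validation, and a synthetic-data generator emulating
    multiplex bead-assay time courses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
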