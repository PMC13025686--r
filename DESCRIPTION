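Package: cigbls
Title: Channel-Independent Anchor Graph-Regularized Broad Learning for Soft Sensors
Version: 0.1.0
Authors@R:
    person("Soft Sensor", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Closed-form wide-network soft sensors for multivariate batch
    processes. Implements a broad learning system whose input variables are
    decoupled into physically isolated feature channels, whose enhancement
    nodes are radial basis functions centred on per-channel K-Means anchors,
    and whose output weights are obtained analytically under a reduced-rank
    anchor-graph manifold constraint. Includes the multi-rate preprocessing
    pipeline (assay-delay alignment, label interpolation, sliding windows,
    stratified batch splits, min-max scaling), grid search and ablation
    drivers, a dense graph-Laplacian oracle for verification, and a seeded
    generator of fed-batch penicillin-like process data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
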