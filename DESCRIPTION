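Package: cystkit
Title: Germline Cyst Topology, Fragmentation and Cytoplasmic Transfer Models
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the formation and breakdown of mouse female germline
    cysts. Builds lineage trees produced by synchronous incomplete mitotic
    divisions (cells connected by intercellular bridges), enumerates the
    fragment sizes produced by single-bridge breakage, and tests observed
    six-cell-fragment frequencies against the random-breakage binomial null
    and its exact Poisson-binomial generalization. Also provides stochastic
    simulators for asymmetric fusome inheritance across cyst divisions,
    nurse-cell-to-oocyte cytoplasmic transfer, and generators of synthetic
    measurement tables, microtubule-gap datasets and voxelized granules for
    volume-quantification testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    ape,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
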