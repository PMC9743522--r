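Package: fusion4c
Title: Virtual 4C and Multi-Caller Consensus Detection of Gene Fusions from Hi-C
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting and characterizing low-frequency gene fusions
    from binned Hi-C contact matrices. Implements virtual 4C viewpoint profiles
    anchored on the two terminals of a target gene (such as BRAF) with
    full-gene background normalization, breakpoint-anchored matrix coarsening,
    iterative-correction balancing, A/B compartment scoring by eigendecomposition
    of the observed/expected correlation matrix, cross-sample compartment
    comparison, and multi-caller structural-variant and RNA fusion consensus
    calling with matched-normal subtraction. Ships a rearrangement-aware
    contact-map simulator (tandem duplications, interchromosomal insertions,
    balanced translocations) with known ground truth so every stage is testable
    without controlled-access data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    igraph,
    yaml,
    jsonlite,
    ape
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    GenomicRanges
Config/testthat/edition: 3
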