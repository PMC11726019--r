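Package: chromoshatter
Title: Chromothripsis Detection from Copy-Number Segments and Structural Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detection of chromothripsis from allele-specific copy-number
    segmentations and structural-variant junctions. Provides a targeted-panel
    caller based on runs of segments oscillating between two copy-number
    states, a whole-genome caller combining interleaved rearrangement
    clusters, oscillating copy number and three statistical tests (fragment
    joins, breakpoint exponentiality, chromosomal enrichment), a cancer-cell-
    fraction estimator with clonality classification, and a seeded generative
    simulator of chromosome shattering, random re-ligation and ecDNA
    amplification for benchmarking both callers against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
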