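Package: amygdex
Title: Developmental Amygdala Expression Filtering and Cell-Type-Resolved
    Differential Expression for Autism Candidate Genes
Version: 0.1.0
Authors@R: person("amygdex", "developers", role = c("aut", "cre"),
    email = "amygdex@example.org")
Description: Integrates scored autism-susceptibility gene lists, filters them
    by developmental amygdala expression in human (BrainSpan-style) and mouse
    (Allen Developing Mouse Brain Atlas-style) data, and identifies
    cell-type-specific differential expression between diagnosis groups in
    single-nucleus RNA-seq using a two-part hurdle model with donor random
    intercepts and likelihood-ratio testing. Ships a synthetic-data generator
    that emulates the statistical structure of all required inputs so the
    complete pipeline is testable without any external download.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    lme4,
    jsonlite,
    optparse,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
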