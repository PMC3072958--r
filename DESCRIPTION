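Package: refstable
Title: Condition-Specific Reference Gene Discovery for RT-qPCR Normalization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Discovery and validation of condition-specific reference
    (housekeeping) genes for RT-qPCR normalization. Ranks probe sets of a
    globally scaled expression compendium by the standard deviation of their
    log2 signal within a user-chosen biological context, constrains candidates
    to an expression band, profiles candidate stability across annotation
    categories, quantifies the overlap of top-ranked stable genes between
    contexts with a permutation test, and validates candidates from Cq data
    using delta-Ct relative quantities, the GeNorm M-value with iterative
    exclusion, and an ungrouped NormFinder stability estimate. Includes a
    synthetic compendium and Cq-experiment generator with planted ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
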