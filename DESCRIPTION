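Package: sigmir
Title: Signature Matching Between Small-Molecule and miRNA Perturbations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Connectivity-map style association scoring between small-molecule
    and miRNA perturbation expression profiles. Builds differential-response
    signatures (fold change, SAM, or amplitude statistics) and ranked response
    patterns from probe-level expression matrices, scores bidirectional
    weighted enrichment of up/down probe sets, combines directional scores
    into per-instance total enrichment scores, aggregates a molecule's
    instances into a Kolmogorov-Smirnov-type Association Score, and assigns
    permutation-based significance. Includes a synthetic-profile generator
    with planted mimic/reversal relationships so the whole pipeline is
    testable without any external corpus, plus readers and writers for the
    TSV/GCT/GMT/RNK dialects the field uses.
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
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
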