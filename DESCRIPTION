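Package: consig
Title: Cross-Study Consensus Marker Signatures for Hippocampal Neural Stem Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparing marker gene lists of neural stem cell (NSC),
    neural progenitor and neuroblast populations across single-cell RNA-seq
    studies. Implements fold-change/adjusted-p marker filtering, pairwise
    gene-list similarity with hierarchical clustering, UpSet-style exclusive
    intersection counting, k-of-n consensus signature extraction, per-cell
    signature scoring (z-score mean and a capped-rank Mann-Whitney-U module
    score with a high-score cutoff, as used for senescence/SASP signatures),
    pseudotime signature profiling with trend statistics, and a synthetic-data
    generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    ape,
    jsonlite,
    yaml,
    methods,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
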