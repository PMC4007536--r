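Package: telifecycle
Title: Transposable Element Family Activity and Life-Cycle Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers the activity and life-cycle stage of transposable element
    (TE) families from genome sequence and stage-structured RNA-seq reads.
    Individual element copies are reconstructed from family terminus matches
    paired by their target-site duplications (TSDs); LTR retrotransposon
    inserts are classified as full-length elements or solo LTRs and dated by
    intra-element LTR divergence; per-family nucleotide diversity (pi) and
    Tajima's D with significance, identical-paralogous-copy counts, copy-age
    profiles from neighbor-joining trees, TSD length and positional
    composition, and stage-specific expression tests (ANOVA plus top-two-stage
    t-test) are computed. A seeded synthetic-genome generator emulates family
    histories (bursts, constant insertion, subfamily splits, solo-LTR
    formation, 5' truncation) for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
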