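Package: polinetseq
Title: NET-seq Occupancy Analysis for RNA Polymerase I on the rDNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: End-to-end analysis of native elongating transcript sequencing
    (NET-seq) libraries for RNA polymerase I on a two-copy ribosomal DNA
    locus: read preprocessing (PCR-duplicate removal, 5' library-format
    filtering with UMI capture, 3' linker trimming), exact-match alignment,
    single-nucleotide occupancy tracks with two-copy collapsing and
    plus-strand normalization, replicate concordance, wild-type versus
    mutant processivity comparison (per-position tests, moving averages,
    Kolmogorov-Smirnov tests), and sequence-context pause analysis with
    permutation-tested difference logos. Includes a synthetic-library
    generator with known per-position occupancy ground truth for
    validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    zoo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
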