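Package: plantmir
Title: Homology-Based Plant miRNA Discovery and Target Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A scriptable pipeline for identifying plant microRNA genes and
    their targets in nucleotide sequence collections (cDNA/EST/GSS). The
    miRNA pipeline validates input sequences, scans them for homologs of
    known mature miRNAs with a lossless mismatch-tolerant seeded search,
    folds candidate primary transcripts, excises stem-loop precursors with
    two-nucleotide 3' overhangs, and validates them against plant precursor
    criteria (MFEI, miRNA:miRNA* duplex mismatches, bulges, multi-loop and
    one-arm rules). The target pipeline scans transcripts for complementary
    sites of mature miRNAs under a weighted binding score with G:U wobble
    handling and positional mismatch rules, then refines sites by
    miRNA:target duplex hybridization. Secondary structure comes from a
    pluggable engine: ViennaRNA when available, or a built-in deterministic
    base-pair-maximization fallback. Includes seeded generators for planted
    hairpin and target fixtures so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    parallel,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    BiocGenerics
Config/testthat/edition: 3
RoxygenNote: 7.3.3
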