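Package: seedgrow
Title: Seed-and-Growth Matching and Quantification for Small RNA Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies mature microRNAs, star strands and antagomirs in
    small RNA sequencing libraries by a seed-and-growth algorithm: reads are
    anchored on exact 16-nucleotide seeds shared with a reference small RNA
    and the perfect match is grown one base at a time at both ends, with the
    remaining bases reported as non-matching 5' and 3' flanks. Includes 3'
    adapter trimming, read collapsing, per-reference occurrence counting
    across replicated two-condition experiments with fold-change and
    Student's t-test comparison, Livak 2^-ddCt relative quantification of
    qPCR Ct tables, an ungapped antagomir/pri-miRNA complementarity scanner
    with optional G:U wobble credit, and a deterministic synthetic read
    simulator with ground-truth abundances for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
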