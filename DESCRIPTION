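Package: miRstress
Title: Two-Condition Small RNA-Seq Analysis of Stress-Responsive Plant miRNAs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for contrasting two small-RNA sequencing
    libraries (e.g. nutrient-sufficient versus nutrient-starved seedlings):
    adapter trimming and read collapsing, perfect-match genome mapping,
    structural-RNA class composition, member-resolved quantification of known
    microRNAs with fold-change response classification, novel-miRNA discovery
    from hairpin-precursor structure criteria with miRNA* support,
    complementarity-based target prediction, and degradome (PARE) cleavage
    validation. Ships a fully specified synthetic-data generator (genome,
    annotations, two-condition libraries, degradome tags, planted truth) so
    every stage is testable without external resources.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    BiocGenerics,
    Biostrings,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
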