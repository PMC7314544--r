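Package: choanoedit
Title: CRISPR/Cas9 Genome-Editing Design and Amplicon Quantification for
    Choanoflagellates
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Toolkit for designing and quantifying CRISPR/SpCas9 genome edits
    in Salpingoeca rosetta and similar non-model organisms: protospacer
    scanning with a target-context motif score and a hairpin folding-energy
    filter, premature-termination-sequence (PTS) cassette validation, design
    of homology-directed repair oligonucleotides, a UMI-deduplicated amplicon
    deep-sequencing pipeline that classifies editing outcomes
    (templated PTS insertion, untemplated indels, SNPs), logistic growth
    fitting by least absolute deviation, limiting-dilution Poisson
    calculations, and a synthetic-data simulator so every stage is testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    BiocGenerics,
    Biostrings,
    S4Vectors,
    GenomicRanges,
    Rcpp,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
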