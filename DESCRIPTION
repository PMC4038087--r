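Package: mesoniv
Title: Mesonivirus Genome Annotation and Species Demarcation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Rule-based annotation of the canonical mesonivirus (+)ssRNA
    genome architecture (overlapping ORFs, transcription-regulatory-sequence
    elements, slippery heptamers, conceptual -1 ribosomal frameshift
    polyproteins, cleavage-site and glycosylation motifs, block insertions
    with imperfect repeats) together with maximum-likelihood pairwise
    evolutionary distances under the WAG amino-acid model on conserved
    replicase domains, threshold-based species demarcation, and
    sliding-window divergence profiles. Includes a synthetic-genome
    generator with a full truth table so every pipeline stage is testable
    without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    methods,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
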