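Package: ervscape
Title: Annotation, Dating and Regulatory Profiling of Endogenous Retrovirus Loci
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A pipeline for characterizing endogenous retrovirus (ERV)
    proviral loci in a host genome against a proviral consensus model:
    k-mer seed-and-extend locus discovery (with PSL import for external
    aligners), per-region structural integrity profiling over the
    5'LTR-gag-pro-pol-env-3'LTR layout, genomic-context classification
    against gene annotation, chi-square tests of chromosomal integration
    bias, molecular-clock integration dating from consensus divergence,
    neighbor-joining phylogeny with bootstrap support for subtype
    assignment, and GREAT-style regulatory-domain gene association with
    hypergeometric over-representation analysis. Includes a synthetic
    genome simulator that plants truncated, mutated proviral copies with
    a machine-readable truth table so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    GenomicRanges,
    jsonlite,
    rtracklayer,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
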