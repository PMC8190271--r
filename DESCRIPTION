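Package: phase22g
Title: Ribosome-Phased 22G-RNA Biogenesis Analytics on Synthetic Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for studying how Argonaute-directed slicing
    primes RNA-dependent RNA polymerase synthesis of antisense 22G small
    RNAs in phase with translating ribosomes. Implements small-RNA
    classification with poly-U tail rescue, ribosome-footprint A/P-site
    codon assignment, translation-efficiency estimation and binning,
    RPF/22G distance periodograms with Fourier period detection, relative
    synonymous codon usage and codon-optimality calling, wobble-adjusted
    tRNA decoding capacity, synonymous CDS optimization, IP-enrichment
    target calling, and gene-body metaprofiles. A seeded synthetic-data
    generator plants codon optimality, codon-dependent ribosome dwell,
    cleavage phasing, poly-U tailing, and IP enrichment so that every
    stage is testable end-to-end without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    GenomicRanges,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
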