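Package: dualstore
Title: Dual-Mode DNA and Nanodot Data Storage: Codecs, Channels and Analytics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: In-silico implementation of a dual-mode molecular data storage
    system that pairs frequently accessed "concise" data, written as nanodot
    bitmaps read by atomic force microscopy, with archival "detailed" data
    stored in surface-immobilized DNA strands. Provides a constraint-screening
    DNA codec (modulation coding against GC-content and homopolymer limits)
    with two-layer Reed-Solomon protection, a Unicode-to-bit-matrix codec with
    AFM height-image synthesis and read-out, simulators for the sequencing,
    thermal-aging and repeated-access channels, a read-decoding pipeline built
    on primer filtering and edit-distance sphere clustering, and areal-density
    and Arrhenius stability analytics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
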