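Package: granulite
Title: Small RNA Classification, ChIP Target Calling and Germ Granule
    Volumetry for C. elegans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale, fully testable re-implementation of the
    computational core of a C. elegans germ-granule small RNA study:
    rule-based calling of piRNA, 22G-RNA and 26G-RNA classes from
    perfectly aligned multi-mapping small RNA reads with fractional
    per-location and per-feature count normalization; differential
    22G-RNA statistics and gene-set fold-enrichment with Fisher's exact
    test; periodate-oxidation (2'-O-methylation) enrichment analysis;
    operon-aware promoter derivation and replicate-consistent ChIP-seq
    target calling; and 3D fluorescence granule segmentation with Li
    auto-thresholding and volume summaries. A seeded synthetic-data
    module generates every pipeline input with ground-truth labels so
    all stages are testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    tiff,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
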