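Package: stretchmap
Title: Stretch-Enhancer Calling and Risk-Variant Prioritization from
    Chromatin-State Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for identifying stretch enhancers from chromatin-state
    segmentations with a Poisson model on consecutive-bin counts, filtering
    for stage-specific stretch enhancers across a developmental time course,
    permutation-based interval overlap enrichment, prioritization of GWAS
    variants falling in regulatory elements with Bonferroni correction and
    distance-based locus grouping, Hi-C contact-matrix balancing and
    donut-background chromatin-loop calling, and assignment of candidate
    target genes by nearest expressed transcription start site or shared
    topologically associated domain. Includes a synthetic-data generator
    that plants known enhancers, variant signals, and loops so the full
    pipeline can be exercised and validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
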