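Package: etsgeo
Title: Promoter Architecture and ETS Motif Geometry in ChIP-Seq Binding Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis of transcription-factor ChIP-Seq binding in relation to
    promoter architecture. Derives 1-kb promoters from gene annotation and
    classifies divergent (bidirectional) and convergent promoter pairs; scores
    strand-aware normalized read coverage over promoters and calls bound
    promoters by a control-derived false discovery threshold with replicate
    intersection; tests 7-mer over-representation in bound promoters by the
    hypergeometric distribution; models binding probability and binding signal
    as functions of ETS motif copy number; and analyses the signed spacing,
    orientation and DNA helical phase of inverted motif pairs, with a
    resampling null for positional significance. A seeded synthetic-data
    generator emits annotation, motif-planted promoter sequences and simulated
    ChIP-Seq reads with known ground truth so the full pipeline is testable
    without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    graphics,
    IRanges,
    methods,
    rtracklayer,
    S4Vectors,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
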