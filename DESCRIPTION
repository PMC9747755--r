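Package: piRNAbind
Title: piRNA Binding-Site Prediction on mRNA by an Additive Hybridization Energy Model
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts PIWI-interacting RNA (piRNA) binding sites on mRNA
    transcripts with an additive hybridization free-energy model that scores
    canonical (G-C, A-U) and noncanonical (G-U wobble, A-C) base pairs over
    the full piRNA length, selects sites by the dG/dGm ratio criterion,
    resolves competition between overlapping sites, merges sites into
    clusters with compaction and region-ratio statistics, selects
    piRNA-gene marker associations by free-energy and ratio thresholds, and
    generates fully synthetic piRNA/transcript datasets with planted sites
    of controlled pair composition for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    BiocGenerics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
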