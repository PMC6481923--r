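Package: twmatrix
Title: Transition Weight Matrix Ranking of Transcription Factors in
    Time-Course Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ranks transcription factors as candidate drivers of a
    time-resolved cell-state transition by combining, across consecutive
    time contrasts, the fold change of each factor, the enrichment of its
    bound targets among differentially expressed genes, and the sign
    coherence between factor and target expression changes (the transition
    weight matrix, TWM). Includes promoter-window assignment of binding
    peaks to genes, a consensus differential-expression rule over supplied
    model statistics, single-cell factor-target coherence analysis with
    tertile contingency tests and variance partitioning, tau
    tissue-specificity classification, and a fully seeded synthetic-data
    generator with planted driver factors for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
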