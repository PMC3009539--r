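Package: PolPromoter
Title: Discriminating Promoter-Associated RNA Pol-II ChIP-seq Enrichment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to discriminate promoter-associated RNA polymerase II
    (Pol-II) ChIP-seq enrichment from enrichment elsewhere in the genome.
    Implements Poisson-background peak calling with false discovery rate
    control, a 39-feature representation of 500 bp windows (sequence
    composition, CpG-island statistics, physico-chemical property scales,
    and CAGE/Pol-II/H3K4me3 tag signal), rule-based construction of labeled
    promoter and non-promoter training sets, ensemble classification
    (bagging and random forest) with sensitivity, positive predictive value,
    Matthews correlation and true-positive-cost evaluation, genome-wide
    promoter annotation with strand-merged calls, gene assignment and
    alternative-promoter summaries, and a fully synthetic data generator so
    every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    randomForest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    rtracklayer
Config/testthat/edition: 3
RoxygenNote: 7.3.3
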