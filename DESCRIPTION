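Package: exactNB
Title: Differential Analysis of Sequence Count Data with a Negative
    Binomial Exact Test
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Differential analysis of count data from high-throughput
    sequencing assays (RNA-Seq, Tag-Seq, comparative ChIP-Seq). Counts are
    modelled as negative binomial with a variance that is the sum of Poisson
    shot noise and a raw (biological) variance term, itself a smooth function
    of the mean fitted by gamma-family local regression. Provides
    median-of-ratios size-factor estimation, an exact test conditioned on the
    per-gene total count, variance estimation modes for designs without
    replication, a variance-stabilizing transformation for sample clustering,
    and a gamma-Poisson simulator with type-I-error and power harnesses.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2
Config/testthat/edition: 3
biocViews: DifferentialExpression, RNASeq, ChIPSeq, Sequencing
RoxygenNote: 7.3.3
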