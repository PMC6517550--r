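Package: growthmodulon
Title: Identification of a Growth Modulon from Growth-Rate-Course RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Pipeline for identifying a bacterial growth modulon from bulk
    RNA-Seq series sampled along growth-rate transitions. Provides
    viability-adjusted differential growth-rate estimation from cell dry
    weight series, relative-log-expression (median-of-ratios) size factors,
    Poisson model-based sample dissimilarity with hierarchical clustering,
    per-condition cubic-in-mu generalized linear model differential
    expression with Benjamini-Hochberg control, cross-condition modulon
    identification with expression-profile clustering, and hypergeometric
    regulon/gene-set over-representation against a regulatory network. A
    negative-binomial synthetic-data generator with planted ground truth
    supports end-to-end recovery testing at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    ape,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    DESeq2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
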