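Package: cagnet
Title: Co-Abundance Group Analysis for Matched Case-Control Microbiome Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and tests gut-microbiota co-abundance groups (CAGs) in
    matched case-control 16S cohorts. Provides one-to-one cohort matching on
    standardized covariates (greedy and optimal assignment), genus filtering,
    group-specific Spearman co-abundance networks with Benjamini-Hochberg
    control, Ward clustering of the pooled correlation matrix into CAGs,
    rank-based differential abundance of CAG summaries, genus-pathway
    bipartite association networks with per-CAG category contrasts, paired
    tests on focal pathway groups (short-chain fatty acid, LPS-associated and
    tryptophan pathways), and random-forest discrimination with Gini
    importance and a Monte-Carlo permutation Shapley attributor. A synthetic
    generator with planted block-correlation structure, group effects,
    matching covariates and a linear genus-to-pathway layer makes every stage
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    randomForest,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    pROC,
    biomformat
Config/testthat/edition: 3
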