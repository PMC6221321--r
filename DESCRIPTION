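Package: odmap
Title: Opioid Dependence Mapping from Time-Course Expression Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pipeline for discovering opioid-dependence-associated genes,
    their candidate transcription regulators, and signature-reversing
    compounds from multi-drug time-course expression data in brain striatum.
    Genes differentially expressed over time are called per drug by local
    quadratic regression with leave-one-out bandwidth selection and
    simultaneous (tube-formula) confidence bands, Bonferroni correction
    across genes, and a fold-change rule; temporal patterns are found by
    Hartigan-Wong k-means with average-silhouette-width model selection;
    hypergeometric over-representation covers functional gene sets and
    regulator target sets derived from binding peaks near transcription
    start/termination sites; per-gene cross-drug expression is associated
    with published drug-harm scores by Pearson correlation and quadratic
    regression; enriched regulators receive fold-change-based dependence
    and harm-association scores; and compound signatures are ranked by a
    connectivity-map-style weighted Kolmogorov-Smirnov reversal statistic
    with permutation p-values. A synthetic-data generator with planted
    ground truth makes every stage verifiable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    jsonlite,
    fgsea,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    mclust,
    cluster,
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
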