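Package: anxclust
Title: Hierarchical Clustering of Country-Level Pre-Exam Anxiety Rates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for clustering country-level mental-health indicators,
    built around the pre-exam anxiety percentages of 15-year-old students
    from 56 countries, stratified by physical-activity status. Provides
    agglomerative hierarchical clustering with Ward, complete, average and
    single linkage, dendrogram cutting by cluster count or by a fraction of
    the maximum merge height, a cluster-validation suite (silhouette widths,
    within- and between-cluster sums of squares with interpretability
    transforms), paired two-group Z comparisons with significance tiers, a
    synthetic-data generator with known cluster structure for end-to-end
    validation, and a reproducible analysis pipeline with newick/JSON
    dendrogram export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    ape,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
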