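Package: occnet
Title: Replicated Co-Occurrence Network Analysis of Microbial Communities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers and compares signed microbial co-occurrence networks
    across groups of samples (e.g. land uses) with a replicated,
    standardized subsampling design. Provides rarefaction, a whole-dataset
    singleton filter and Shannon diversity indices; pairwise Spearman
    correlation with Benjamini-Hochberg false-discovery-rate control and
    sign assignment; signed-graph topology metrics (links, positive and
    negative links, connectance, average path length, average degree) under
    explicitly configurable conventions; ANOVA with Tukey HSD compact
    letter displays for cross-group comparison; hub (keystone) genus
    identification by pairwise Kruskal-Wallis rank tests with Bonferroni
    correction; and a synthetic community generator with planted, signed
    network structure that supplies ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils,
    vegan,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
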