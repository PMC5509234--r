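Package: otunet
Title: Diversity, Ordination and Permutation Co-Occurrence Networks for
    Amplicon Count Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream statistical analysis of 16S rRNA amplicon OTU count
    tables from low-biomass samples such as bronchial brushings: reagent
    contamination screening by negative Spearman correlation of OTU relative
    abundance with amplicon concentration, read-depth control by discarding
    shallow libraries and rarefying to a common depth, genus-level
    aggregation with rare-genus filtering, Hellinger transformation,
    Bray-Curtis ordination (PCoA) and PERMANOVA, seasonal batch correction by
    per-season median subtraction, two-sided Wilcoxon-Mann-Whitney group
    screens with Benjamini-Hochberg adjustment, and compositionality-aware
    permutation-null Spearman co-occurrence networks with connected-component
    community detection. Includes a synthetic-data generator with planted
    ground truth (co-varying genus blocks, group effects, seasonal shifts,
    contaminant OTUs) so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    biomformat,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
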