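Package: cazyclust
Title: CAZyme Family Profiling and Phenotype Concordance for Bacteroides
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative-genomics pipeline for grouping Bacteroides species by
    the composition of their glycosaminoglycan-degrading enzyme families and
    asking how well those groups predict a binary degradation phenotype.
    Provides greedy centroid (UCLUST-style) clustering of enzyme-family
    protein sequences at a configurable identity threshold, species-by-cluster
    presence/absence profiles, Jaccard distance matrices merged across
    families, hierarchical clustering of species with partition cutting,
    and partition-vs-phenotype concordance metrics (adjusted Rand index,
    normalized mutual information, majority-vote precision/recall/F1/accuracy
    with Mixed/NA exclusion). Also includes a strain-level homolog
    conservation screen with identity and coverage filters, a volcano-style
    differential-expression classifier with Benjamini-Hochberg adjustment,
    and synthetic-data generators with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
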