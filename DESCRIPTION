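Package: seedmet
Title: Seed Metabolomics, Germination Vigor and Putative QTL Analysis for
    Introgression-Line Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An analysis pipeline linking the primary-metabolite profile of
    dry seeds to germination vigor in an introgression-line (IL) population.
    Raw GC-MS peak heights are normalized to relative metabolite content
    (seed-weight, total-sum and per-run-block median normalization), log
    transformed and completed by iterative low-rank imputation. Germination
    plate counts are summarized into final percent, T50 and within-plate
    uniformity, and salinity-response fold changes. Putative QTLs are called
    by Welch t-tests of each IL against the recurrent control line under a
    strict or permissive (alpha over square root of n) Bonferroni rule,
    including fold-change QTLs for the salinity response. Signed Spearman
    correlation networks of metabolites and germination traits are
    partitioned by Walktrap communities and frustration-minimizing signed
    bipartition into two antagonistic metabolite sets, and the metabolic
    profile is related to germination by PCA, k-means clustering with
    chi-square enrichment, and germination-group contrasts. A synthetic-data
    generator reproduces the assumed statistical structure with known ground
    truth so the whole pipeline can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
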