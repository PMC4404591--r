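Package: apportionr
Title: Apportionment of Gene Expression Variation Within and Among Groups
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Partitions per-gene expression variation from replicated
    RNA-seq designs into intra-individual, inter-individual and
    among-group components using a nested model-II analysis of variance
    with technical covariates. Provides the sums-of-squares (Nst, Nit,
    Net, Nis, Nig) and variance-component (Mst, Mit, Met) apportionment
    statistics, permutation null distributions for gene-level and
    mean-level significance, an artificial-gene resampling null for
    inter-individual variance, classification of expression profiles
    consistent with directional, balancing, stabilizing or diversifying
    selection, replicate-pairing quality control, structure analyses
    (PCA with trait screening, UPGMA population distance trees, k-means
    profile partitioning), and a negative-binomial simulator of
    hierarchical experiments with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    cluster,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
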