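Package: triadclust
Title: Combinatorial Clustering of Binding-Site Residue Triads for
    Semi-Supervised Affinity Annotation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Enumerates all 3-position subsets of an aligned protein
    binding site, clusters the resulting residue-triad substructures by a
    combined geometric (side-chain-centroid least RMSD) and
    physicochemical (pharmacophore feature) dissimilarity, selects
    label-pure highly predictive clusters, and predicts binary annotation
    labels (such as inhibitor binding) for unlabeled proteins by vote
    aggregation and a linear support-vector decision boundary.  Includes
    identity-clustered cross-validation, ROC/PR/enrichment evaluation, a
    seeded synthetic-data generator with planted substructure clusters,
    and ggplot2 visualisations of embeddings, purity distributions and
    vote space.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    mclust,
    e1071,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    bio3d,
    Biostrings,
    cluster,
    pROC,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
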