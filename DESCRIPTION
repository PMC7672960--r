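Package: braingcn
Title: Population-Graph Convolutional Networks for Brain-Imaging
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Classifies subjects (early mild cognitive impairment versus
    normal controls) from region-level brain-imaging features. From
    per-region grey-matter volumes and resting-state fMRI time series it
    derives grey-matter-volume and nodal shortest-path-length features,
    selects features jointly across the two modalities with an
    l2,1-regularized multi-task group LASSO, builds a population graph of
    subjects whose edges combine imaging-feature similarity with
    agreement on non-imaging phenotypes (sex, age, MMSE), and classifies
    subjects transductively with a Chebyshev spectral graph convolutional
    network. Includes a synthetic-cohort generator with planted regional
    atrophy and weakened within-module connectivity, repeated stratified
    cross-validation with leakage auditing, and comparison feature
    selectors (univariate t-test, single-task LASSO).
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
    glmnet,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
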