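Package: latentomics
Title: Multi-Omics Integration with Stacked Variational Autoencoders
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates gene expression, somatic mutation, and copy-number
    matrices into a shared set of non-negative latent factors using a stacked
    variational autoencoder with KL warm-up, trained by minibatch gradient
    descent. Includes network smoothing of binary mutation profiles over a
    protein-protein interaction graph by random walks with restarts, latent
    factor interpretation (feature association, clinical relevance via Cox
    regression, hypergeometric over-representation tests), a benchmark suite
    (nested-CV SVM subtype prediction, k-means clustering with adjusted mutual
    information, survival concordance, compound model-selection score), a
    nearest-neighbor fitness test for cancer cell lines as tumor models, and a
    synthetic multi-omics data generator with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    e1071,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
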