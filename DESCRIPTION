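Package: spliceSSL
Title: Ensemble-Based Semi-Supervised Learning for Imbalanced Splice Site
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Self-training and co-training ensembles of categorical Naive
    Bayes classifiers for acceptor splice site prediction from highly
    imbalanced sequence data. Implements balanced-subset ensembles with
    eight semi-supervised variants that differ in pseudo-label selection
    (positive-and-negative versus positive-only augmentation) and routing
    (shared versus distributed among ensemble members), a supervised
    lower-bound ensemble baseline, positional nucleotide and 3-mer feature
    views, a synthetic acceptor-site data generator with controllable
    imbalance and signal strength, and an evaluation harness based on
    stratified cross-validation, minority-class area under the
    precision-recall curve, and paired t-tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    e1071,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
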