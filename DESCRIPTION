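Package: rknnfs
Title: Random KNN Classification and Feature Selection for High-Dimensional Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Random KNN: an ensemble classifier built from many k-nearest-neighbour
    base learners, each restricted to a small random subspace of the features and
    combined by majority-of-majority voting. Feature relevance is scored by
    bidirectional voting: each base classifier's accuracy is credited back to the
    features it used, and a feature's "support" is its mean accuracy over the base
    classifiers containing it. On top of the support ranking the package provides
    RKNN-FS, a two-stage backward elimination procedure (a fast geometric stage
    followed by a one-at-a-time linear stage) for gene selection in "small n,
    large p" expression data, external leave-one-out cross-validation with
    per-fold re-selection, stability summaries, a synthetic-data generator with
    planted informative features, and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
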