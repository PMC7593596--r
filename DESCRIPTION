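Package: REOsig
Title: Reversal Gene-Pair Signature Discovery from Relative Expression
    Orderings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Rank-based discovery and application of diagnostic gene-pair
    signatures from within-sample relative expression orderings (REOs).
    Detects gene pairs whose ordering is stable within a sample group,
    intersects stability across subgroups of a class, extracts reversal
    pairs whose stable ordering flips between tumor and non-tumor classes,
    encodes samples as ternary REO profiles, ranks pairs by
    minimum-redundancy-maximum-relevance mutual information, chooses a
    signature size by incremental feature selection under cross-validated
    classifiers, and evaluates transfer of the signature across expression
    platforms. Includes a synthetic expression generator with planted
    reversal pairs for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Rcpp,
    e1071,
    pROC,
    rpart,
    randomForest
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
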