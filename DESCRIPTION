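Package: sflscreen
Title: Lexicogrammar-Based Differentiation of Autism-Spectrum Speech
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for differentiating autism-spectrum (AS) from non-AS speakers
    from tokenized spoken-language transcripts annotated with a 147-type
    systemic-functional-linguistics (SFL) lexicogrammar tag schema. Provides the
    tag taxonomy and stable tag indexing, JSONL/TSV corpus input and output,
    tag-frequency featurization, a Bi-LSTM multi-label sequence tagger for
    automatic annotation, four diagnostic classifiers (tag-frequency logistic
    regression and three Bi-LSTM variants over tag, text, and concatenated
    tag+text embeddings), a nested leave-one-out evaluation protocol that
    retrains both tagger and classifier per fold, the associated metric suite
    (accuracy with Wald intervals, precision, sensitivity, specificity, AUC),
    paired McNemar comparisons, and a synthetic two-group tagged-corpus
    generator with controllable per-tag effect sizes for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
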