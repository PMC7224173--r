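Package: synthnotes
Title: Key-Phrase-Conditioned Generation and Evaluation of Artificial Clinical Text
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates artificial clinical free text (discharge-summary style
    documents) by conditioning a sequence-to-sequence gap-filling model on
    RAKE key phrases extracted from genuine paragraphs plus per-sentence
    clinical metadata, and evaluates the result three ways: intrinsic
    text-preservation metrics (ROUGE-L recall, corpus BLEU, translation edit
    rate, perplexity, sentence lengths, TER-bin CDFs), a memorisation audit
    that measures how often rare versus frequent training n-grams reappear in
    conditioning inputs and regenerated outputs, and an extrinsic utility
    comparison that trains bag-of-words, topic-model and convolutional
    classifiers on genuine versus artificial data and compares per-class F1
    distributions with the two-sample Kolmogorov-Smirnov test. Includes a
    synthetic-corpus generator so the full pipeline is testable without
    access-restricted clinical data, patient-grouped splitting, a
    line-delimited corpus exchange format, and an end-to-end pipeline runner
    with reproducible seeding and run manifests.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    randomForest,
    stats,
    utils,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
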