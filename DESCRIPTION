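Package: textlc
Title: Learning-Curve Analysis of Bag-of-Words Disease Text Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying text classifiers under data scarcity on
    long-tailed single-label corpora such as patient disease descriptions.
    Implements TFIDF bag-of-words and embedding-averaged document
    representations, a chi-square feature-selection plus synonym-expansion
    representation that strengthens class-indicative features via word-vector
    cosine similarity, one-vs-rest linear support vector machine training, a
    per-class stratified learning-curve harness with macro-averaged F1 and
    area-under-learning-curve summaries, rare-class sub-analyses, paired
    Fisher randomization tests for method comparison, and a reproducible
    synthetic generator of long-tailed corpora with synonym-cluster embedding
    geometry.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    e1071,
    graphics,
    grDevices,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
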