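Package: elgram
Title: Cortical-Column Encoder Layer for Grammatical Category Emergence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates a cortical patch ("encoder layer") of cortical columns
    that fuses distributional-semantic word embeddings (proximal afferent
    dendrites modelled as per-column self-organizing maps), coarse
    content/function/verb word-category codes (apical distal dendrites) and
    its own previous activation (lateral distal dendrites) into sparse
    distributed representations of words in sentence context. Distal dendrites
    carry weighted potential synapses grouped into per-column branches;
    branches spike independently, partially depolarized units win a
    winner-take-all race within their afferently excited cluster, and
    prediction failure triggers massive firing events. Includes STDP-like
    potentiation/depression with periodic homeostatic pruning, a lesioned
    variant with lateral connections stripped, a synthetic generator of
    clustered embeddings and tagged corpora with ambiguous homographs, readers
    and writers for word2vec and SVMlight formats, and a linear-SVM evaluation
    protocol (C sweep, five-fold cross-validation, per-tag disaggregation,
    paired t-tests with Holm-Bonferroni correction) for fine-grained
    grammatical tag classification.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    e1071,
    jsonlite,
    Matrix,
    methods,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
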