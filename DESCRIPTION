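Package: genecontext
Title: Contextualizing Genes with Text-Mined Co-Occurrence Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A literature-mining toolkit for gene panel discovery.
    Reads entity-annotated biomedical abstracts in the PubTator exchange
    format, tags additional concepts through the MeSH thesaurus hierarchy,
    extracts three-sentence gene context windows, builds a sparse
    gene x term-feature TF-IDF matrix, selects panel-characteristic
    term features with an upper-tail hypergeometric test, summarises the
    matrix with non-negative matrix factorization topic models, and
    benchmarks panel-membership classifiers with stratified cross-validation.
    Ships a fully synthetic corpus generator with ground-truth manifests
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    data.table,
    jsonlite,
    class,
    e1071,
    kernlab,
    rpart,
    randomForest,
    nnet
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
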