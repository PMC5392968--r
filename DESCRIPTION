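Package: meshrank
Title: Learning-to-Rank Automatic Subject Indexing with Hierarchical
    Controlled Vocabularies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Automatic subject indexing of scientific abstracts against a
    hierarchical controlled vocabulary such as the Medical Subject Headings
    (MeSH). Candidate descriptors are harvested from k-nearest-neighbour
    documents, from one cost-sensitive linear classifier per frequent label
    (modified Huber loss), and from an optional external recommender; the
    merged candidate list is ranked by a LambdaMART gradient-boosted tree
    ensemble over retrieval features (neighbourhood statistics, term-name
    overlap, IBM Model 1 translation probabilities, BM25 and
    translation-based query likelihood, synonym matches), then pruned with
    age check-tag injection, parent-term removal and a log-weighted score
    cut-off. Includes a synthetic vocabulary and corpus generator so the
    whole pipeline can be trained and evaluated without external data.
License: MIT
Encoding: UTF-8
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
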