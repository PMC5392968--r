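test_that("candidate generation unions the three sources with OR-ed provenance", {
  pdoc <- mk_pdoc(c("sig", "other"), "q")
  nbrs <- data.frame(doc_id = c("n1", "n2"), similarity = c(0.9, 0.8))
  anns <- list(n1 = c("D1", "D2"), n2 = "D2")
  battery <- mk_battery(list(
    mk_label_model("D2", c(sig = 2), theta = -1),   # fires (score 2/sqrt(2)-1>0)
    mk_label_model("D3", c(sig = 2), theta = -1),   # fires
    mk_label_model("D9", c(zzz = 1), theta = -1)))  # does not fire
  cands <- generate_candidates(pdoc, nbrs, anns, battery,
                               external = c("D4", "D4"))
  expect_identical(cands$descriptor_id, c("D1", "D2", "D3", "D4"))
  d2 <- cands[cands$descriptor_id == "D2", ]
  expect_true(d2$from_knn && d2$from_classifier && !d2$from_external)
  expect_true(cands$from_external[cands$descriptor_id == "D4"])
  expect_false(cands$from_knn[cands$descriptor_id == "D3"])
  # scores attached wherever a model exists, with presence indicator
  expect_true(all(cands$classifier_present[cands$descriptor_id %in% c("D2", "D3")]))
  expect_false(any(cands$classifier_present[cands$descriptor_id %in% c("D1", "D4")]))
  expect_identical(cands$classifier_score[cands$descriptor_id == "D1"], 0)
  # at least one source flag per candidate
  expect_true(all(cands$from_knn | cands$from_classifier | cands$from_external))
})

test_that("no firing source yields an empty, warned candidate list", {
  pdoc <- mk_pdoc("lonely", "q")
  nbrs <- data.frame(doc_id = character(), similarity = numeric())
  expect_warning(cands <- generate_candidates(pdoc, nbrs, list()),
                 "no candidate source")
  expect_identical(nrow(cands), 0L)
})

feature_fixture <- function() {
  vocab <- new_vocabulary(list(
    new_descriptor("D1", "sig", synonyms = "marker phrase",
                   tree_numbers = "A"),
    new_descriptor("D2", "sig other", tree_numbers = "B"),
    new_descriptor("D3", "unrelated", tree_numbers = "C")))
  doc <- new_document("q", title = "sig", abstract = "")
  pdoc <- preprocess(doc, stemmer = "none", stopwords = character())
  tt <- mk_translation_table(matrix(c(0.6, 0.4), 2, 1,
                                    dimnames = list(c("sig", "other"), "sig")))
  bg <- background_stats(list(q = pdoc))
  list(vocab = vocab, doc = doc, pdoc = pdoc, tt = tt, bg = bg)
}

test_that("feature extraction follows the stated definitions", {
  fx <- feature_fixture()
  nbrs <- data.frame(doc_id = c("n1", "n2", "n3", "n4"),
                     similarity = c(0.5, 0.4, 0.3, 0.2))
  anns <- list(n1 = "D1", n2 = c("D1", "D2"), n3 = "D1", n4 = character())
  cands <- data.frame(descriptor_id = c("D1", "D2", "D3"),
                      from_knn = c(TRUE, TRUE, FALSE),
                      from_classifier = FALSE,
                      from_external = c(FALSE, FALSE, TRUE),
                      classifier_score = c(0.7, 0, 0),
                      classifier_present = c(TRUE, FALSE, FALSE),
                      stringsAsFactors = FALSE)
  f <- candidate_features(fx$pdoc, fx$doc, cands, fx$vocab, nbrs, anns,
                          fx$tt, fx$bg, stemmer = "none",
                          stopwords = character())
  expect_identical(colnames(f), feature_schema())
  # D1 in neighbours n1, n2, n3 with sims 0.5 + 0.4 + 0.3
  expect_equal(unname(f["D1", "nbr_freq"]), 3)
  expect_equal(unname(f["D1", "nbr_sim_sum"]), 1.2)
  # single-token name present in a 1-token title: unigram 1, no bigrams
  expect_equal(unname(f["D1", "unigram_overlap"]), 1)
  expect_equal(unname(f["D1", "bigram_overlap"]), 0)
  # "sig other": one of two name unigrams present; bigram absent
  expect_equal(unname(f["D2", "unigram_overlap"]), 0.5)
  expect_equal(unname(f["D2", "bigram_overlap"]), 0)
  # name token absent everywhere, no synonyms present
  expect_equal(unname(f["D3", "unigram_overlap"]), 0)
  expect_equal(unname(f["D3", "synonym_match"]), 0)
  # synonym only fires on substring presence
  expect_equal(unname(f["D1", "synonym_match"]), 0)
  # translation: max over doc tokens of t(name_token | w), product-aggregated
  expect_equal(unname(f["D1", "translation_prob"]), 0.6)
  expect_equal(unname(f["D2", "translation_prob"]), 0.6 * 0.4)
  # provenance features copied through
  expect_equal(unname(f["D1", "classifier_score"]), 0.7)
  expect_equal(unname(f["D1", "classifier_present"]), 1)
  expect_equal(unname(f["D3", "external_flag"]), 1)
  # invariants
  expect_true(all(f[, "nbr_freq"] <= nrow(nbrs)))
  expect_true(all(f[, "nbr_sim_sum"] <= f[, "nbr_freq"] * max(nbrs$similarity) + 1e-12))
})

test_that("synonym matching is case-folded substring presence", {
  fx <- feature_fixture()
  doc <- new_document("q", title = "A Marker Phrase appears", abstract = "x")
  pdoc <- preprocess(doc, stemmer = "none", stopwords = character())
  cands <- data.frame(descriptor_id = "D1", from_knn = TRUE,
                      from_classifier = FALSE, from_external = FALSE,
                      classifier_score = 0, classifier_present = FALSE)
  f <- candidate_features(pdoc, doc, cands, fx$vocab,
                          data.frame(doc_id = "n1", similarity = 0.5),
                          list(n1 = "D1"), fx$tt, fx$bg,
                          stemmer = "none", stopwords = character())
  expect_equal(unname(f["D1", "synonym_match"]), 1)
})

test_that("unknown descriptors are rejected and empty candidate lists pass through", {
  fx <- feature_fixture()
  nbrs <- data.frame(doc_id = "n1", similarity = 0.5)
  cands <- data.frame(descriptor_id = "NOPE", from_knn = TRUE,
                      from_classifier = FALSE, from_external = FALSE,
                      classifier_score = 0, classifier_present = FALSE)
  expect_error(candidate_features(fx$pdoc, fx$doc, cands, fx$vocab, nbrs,
                                  list(n1 = "D1"), fx$tt, fx$bg),
               "unknown descriptor")
  empty <- generate_candidates(mk_pdoc("sig", "q"),
                               data.frame(doc_id = "n1", similarity = 1),
                               list(n1 = "D1"))
  f <- candidate_features(fx$pdoc, fx$doc, empty[0, ], fx$vocab, nbrs,
                          list(n1 = "D1"), fx$tt, fx$bg)
  expect_identical(nrow(f), 0L)
})

test_that("candidate union dominates every single source on gold coverage", {
  fx <- get_small_fixture()
  model <- fx$model
  docs <- fx$test[1:15]
  pdocs <- preprocess_corpus(docs)
  for (id in names(pdocs)) {
    nbrs <- knn_retrieve(model$index, pdocs[[id]], model$config$knn)
    ext <- external_recommend(pdocs[[id]], model$vocab, model$term_tokens)
    cands <- generate_candidates(pdocs[[id]], nbrs, model$index$annotations,
                                 model$battery, ext)
    gold <- docs[[id]]$gold_terms
    knn_only <- unique(unlist(model$index$annotations[nbrs$doc_id]))
    in_cand <- sum(gold %in% cands$descriptor_id)
    expect_gte(in_cand, sum(gold %in% knn_only))
    expect_gte(in_cand, sum(gold %in% ext))
  }
})

test_that("feature lists round-trip through the TSV exchange format", {
  set.seed(42)
  lists <- list(
    docA = list(features = matrix(stats::runif(33), 3, 11,
                                  dimnames = list(c("D1", "D2", "D3"),
                                                  feature_schema())),
                labels = c(1L, 0L, 0L)),
    docB = list(features = matrix(stats::runif(22), 2, 11,
                                  dimnames = list(c("D1", "D4"),
                                                  feature_schema())),
                labels = c(0L, 1L)))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_feature_lists(lists, path)
  back <- read_feature_lists(path)
  expect_setequal(names(back), names(lists))
  for (id in names(lists)) {
    expect_equal(back[[id]]$features, lists[[id]]$features, tolerance = 1e-15)
    expect_identical(as.integer(back[[id]]$labels), lists[[id]]$labels)
  }
})
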