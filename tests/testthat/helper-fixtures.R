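# Shared fixtures: a tiny hand-built hierarchy, raw processed docs, and a
# lazily trained small pipeline model reused across test files.

toy_vocab <- function() {
  new_vocabulary(list(
    new_descriptor("TA", "Alpha", tree_numbers = "A"),
    new_descriptor("TA1", "Alpha One", synonyms = "first alpha",
                   tree_numbers = "A.1"),
    new_descriptor("TA11", "Alpha One One", tree_numbers = "A.1.1"),
    new_descriptor("TB", "Beta", tree_numbers = "B"),
    new_descriptor("TB1", "Beta One", tree_numbers = "B.1")))
}

# processed doc straight from tokens (no stemming, no stop words)
mk_pdoc <- function(tokens, id = "q") {
  tf <- if (length(tokens)) table(tokens) else integer()
  structure(list(doc_id = id, tokens = tokens,
                 tf = stats::setNames(as.integer(tf), names(tf)),
                 length = length(tokens)),
            class = "processed_doc")
}

mk_label_model <- function(id, w, theta = 0) {
  structure(list(descriptor_id = id, w = w, theta = theta),
            class = "label_model")
}

mk_battery <- function(models) {
  names(models) <- vapply(models, `[[`, "", "descriptor_id")
  structure(list(models = models,
                 skipped = data.frame(label = character(),
                                      reason = character()),
                 config = svm_config()),
            class = "classifier_battery")
}

mk_translation_table <- function(tmat) {
  structure(list(t = tmat, term_vocab = rownames(tmat),
                 doc_vocab = colnames(tmat), ll = numeric(0)),
            class = "translation_table")
}

# random hierarchy over n nodes: each non-root attaches under a previous node
random_tree_vocab <- function(n, seed) {
  set.seed(seed)
  trees <- character(n)
  kids <- integer(n)
  trees[1] <- "1"
  n_roots <- 1L
  for (i in seq_len(n)[-1]) {
    if (stats::runif(1) < 0.25) {
      n_roots <- n_roots + 1L
      trees[i] <- as.character(n_roots)
    } else {
      p <- sample.int(i - 1L, 1)
      kids[p] <- kids[p] + 1L
      trees[i] <- paste(trees[p], kids[p], sep = ".")
    }
  }
  new_vocabulary(lapply(seq_len(n), function(i)
    new_descriptor(sprintf("N%02d", i), sprintf("Node %02d", i),
                   tree_numbers = trees[i])))
}

# brute-force ancestor oracle on dot components
oracle_is_ancestor <- function(v, a, b) {
  ta <- lapply(v$descriptors[[a]]$tree_numbers,
               function(x) strsplit(x, ".", fixed = TRUE)[[1]])
  tb <- lapply(v$descriptors[[b]]$tree_numbers,
               function(x) strsplit(x, ".", fixed = TRUE)[[1]])
  for (x in ta) for (y in tb)
    if (length(y) > length(x) && identical(y[seq_along(x)], x))
      return(TRUE)
  FALSE
}

# small trained pipeline, built once per test run
small_model_env <- new.env()
get_small_fixture <- function() {
  if (is.null(small_model_env$fx)) {
    spec <- fixture_spec(n_docs = 250, seed = 11)
    vocab <- make_vocabulary(spec)
    corpus <- make_corpus(spec, vocab)
    cfg <- mesh_config(seed = 5, n_rank_docs = 120,
                       svm = svm_config(epochs = 8),
                       ranker = list(n_trees = 30, max_leaves = 10,
                                     learning_rate = 0.1, min_leaf_obs = 1))
    model <- mesh_train(corpus[1:200], vocab, cfg, quiet = TRUE)
    small_model_env$fx <- list(spec = spec, vocab = vocab, corpus = corpus,
                               cfg = cfg, model = model,
                               train = corpus[1:200], test = corpus[201:250])
  }
  small_model_env$fx
}
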