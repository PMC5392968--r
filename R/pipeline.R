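# End-to-end orchestration: training the full model bundle (index,
# classifier battery, translation table, background stats, ranker),
# per-document prediction with post-processing, corpus evaluation, and a
# disk-artifact front end used by the command-line wrapper.

#' Pipeline configuration
#'
#' All randomness flows from `seed`; every component derives its own
#' stream from it, so outputs are identical across runs and worker
#' counts.
#'
#' @param seed master seed.
#' @param date_floor optional `Date` restricting the neighbour index and
#'   label frequencies to recently annotated documents.
#' @param knn a [knn_config()].
#' @param svm an [svm_config()] (its seed is overridden by `seed`).
#' @param n_classifier_labels how many frequent labels get a classifier
#'   (reference setting 20,000; capped at the vocabulary size).
#' @param ibm_iters IBM Model 1 EM iterations.
#' @param ibm_sample,bg_sample caps on the documents used to fit the
#'   translation table and background statistics (the reference setup
#'   uses a ~60,000 document sample).
#' @param n_rank_docs documents sampled to train the ranker (reference
#'   setting 5,000).
#' @param ranker list of LambdaMART settings (`n_trees`, `max_leaves`,
#'   `learning_rate`, `min_leaf_obs`).
#' @param prune a [pruning_config()].
#' @param external `"pseudo"` to use the built-in name-overlap
#'   recommender as the external channel, `"none"` to disable it.
#' @param stemmer,stopwords text preprocessing settings.
#' @return a `mesh_config` list.
#' @export
mesh_config <- function(seed = 1, date_floor = NULL,
                        knn = knn_config(),
                        svm = svm_config(),
                        n_classifier_labels = 20000,
                        ibm_iters = 20, ibm_sample = 60000,
                        bg_sample = 60000, n_rank_docs = 5000,
                        ranker = list(n_trees = 300, max_leaves = 10,
                                      learning_rate = 0.1, min_leaf_obs = 1),
                        prune = pruning_config(),
                        external = c("pseudo", "none"),
                        stemmer = "porter",
                        stopwords = default_stopwords()) {
  external <- match.arg(external)
  svm$seed <- as.integer(seed)
  structure(list(seed = as.integer(seed), date_floor = date_floor,
                 knn = knn, svm = svm,
                 n_classifier_labels = n_classifier_labels,
                 ibm_iters = ibm_iters, ibm_sample = ibm_sample,
                 bg_sample = bg_sample, n_rank_docs = n_rank_docs,
                 ranker = ranker, prune = prune, external = external,
                 stemmer = stemmer, stopwords = stopwords),
            class = "mesh_config")
}

.external_for <- function(model, pdoc, external) {
  if (!is.null(external)) {
    if (is.list(external)) return(external[[pdoc$doc_id]] %||% character())
    return(as.character(external))
  }
  if (model$config$external == "pseudo")
    external_recommend(pdoc, model$vocab, model$term_tokens)
  else
    character()
}

.candidate_lists <- function(model, pdocs, docs, external = NULL,
                             with_labels = FALSE) {
  out <- vector("list", length(pdocs))
  names(out) <- names(pdocs)
  for (id in names(pdocs)) {
    pdoc <- pdocs[[id]]
    nbrs <- knn_retrieve(model$index, pdoc, model$config$knn)
    ext <- .external_for(model, pdoc, external)
    cands <- suppressWarnings(
      generate_candidates(pdoc, nbrs, model$index$annotations,
                          model$battery, ext))
    feats <- candidate_features(pdoc, docs[[id]], cands, model$vocab, nbrs,
                                model$index$annotations, model$tt, model$bg,
                                term_tokens = model$term_tokens)
    out[[id]] <- list(features = feats, candidates = cands,
                      neighbours = nbrs,
                      labels = if (with_labels)
                        as.integer(cands$descriptor_id %in%
                                     docs[[id]]$gold_terms))
  }
  out
}

#' Train the full indexing model
#'
#' Builds, in order: the recency-filtered neighbour similarity index;
#' label frequencies; background collection statistics; the per-label
#' classifier battery; the IBM Model 1 translation table (descriptor
#' names vs. document text of annotated training documents); and the
#' LambdaMART ranker trained on candidate lists of a sampled subset of
#' training documents.
#'
#' @param corpus named list of annotated `mesh_document` (training set).
#' @param vocab a `mesh_vocabulary`.
#' @param config a [mesh_config()].
#' @param quiet suppress progress messages.
#' @return an object of class `mesh_model`.
#' @export
mesh_train <- function(corpus, vocab, config = mesh_config(),
                       quiet = FALSE) {
  say <- function(...) if (!quiet) message("[mesh_train] ", ...)
  corpus <- .check_corpus(corpus)
  vocab <- set_label_frequencies(vocab, corpus, config$date_floor)
  say("building index over ", length(corpus), " documents")
  index <- build_index(corpus, date_floor = config$date_floor,
                       stemmer = config$stemmer,
                       stopwords = config$stopwords, seed = config$seed)
  term_tokens <- .term_token_cache(vocab, config$stemmer, config$stopwords)
  say("background statistics")
  bg <- background_stats(index$pdocs, sample_n = config$bg_sample,
                         seed = config$seed)
  say("training classifiers for up to ", config$n_classifier_labels,
      " labels")
  battery <- train_all(index$pdocs, index$annotations, vocab,
                       n_labels = min(config$n_classifier_labels,
                                      length(vocab)),
                       cfg = config$svm)
  say("training translation table")
  set.seed(config$seed)
  tt_ids <- index$doc_ids
  if (length(tt_ids) > config$ibm_sample)
    tt_ids <- sort(sample(tt_ids, config$ibm_sample))
  pairs <- list()
  for (id in tt_ids) {
    for (term in index$annotations[[id]]) {
      if (!term %in% names(term_tokens)) next
      if (!length(term_tokens[[term]])) next
      pairs[[length(pairs) + 1L]] <- list(term = term_tokens[[term]],
                                          doc = index$pdocs[[id]]$tokens)
    }
  }
  tt <- train_ibm1(pairs, iters = config$ibm_iters)
  model <- structure(list(vocab = vocab, index = index, bg = bg,
                          battery = battery, tt = tt, ranker = NULL,
                          term_tokens = term_tokens, config = config,
                          age_rules = default_age_rules(vocab)),
                     class = "mesh_model")
  say("building ranker training lists")
  set.seed(config$seed + 1L)
  rank_ids <- index$doc_ids
  if (length(rank_ids) > config$n_rank_docs)
    rank_ids <- sort(sample(rank_ids, config$n_rank_docs))
  lists <- .candidate_lists(model, index$pdocs[rank_ids], corpus[rank_ids],
                            with_labels = TRUE)
  lists <- Filter(function(l) nrow(l$features) >= 2, lists)
  say("training LambdaMART on ", length(lists), " lists")
  rk <- config$ranker
  model$ranker <- train_lambdamart(
    lapply(lists, function(l) list(features = l$features,
                                   labels = l$labels)),
    n_trees = rk$n_trees, max_leaves = rk$max_leaves,
    learning_rate = rk$learning_rate, min_leaf_obs = rk$min_leaf_obs,
    seed = config$seed)
  say("done")
  model
}

#' @export
print.mesh_model <- function(x, ...) {
  cat("mesh_model:", x$index$n_docs, "training documents,",
      length(x$battery$models), "classifiers,",
      length(x$ranker$trees %||% list()), "ranker trees\n")
  invisible(x)
}

#' Predict descriptors for new documents
#'
#' For each document: retrieve neighbours, merge the candidate sources,
#' extract features, score with the ranker (scores are mapped through a
#' logistic to the positive scale assumed by the cut-off rule), and
#' post-process (age check tags, specificity pruning, score cut-off).
#' With `baseline = "nbr_freq"` the ranker is replaced by the neighbour
#' frequency of each candidate under identical pruning, giving the
#' k-NN-only reference ranking.
#'
#' @param model a `mesh_model` (must contain a trained ranker unless
#'   `baseline` is used).
#' @param docs named list of `mesh_document` to index.
#' @param external optional external recommendations: a named list
#'   doc_id -> descriptor ids (overrides the configured channel).
#' @param baseline `"none"` (use the ranker) or `"nbr_freq"`.
#' @return named list of `prediction_list` objects.
#' @export
mesh_predict <- function(model, docs, external = NULL,
                         baseline = c("none", "nbr_freq")) {
  baseline <- match.arg(baseline)
  if (baseline == "none" && is.null(model$ranker))
    stop("model has no trained ranker; run mesh_train (mode 'train') first")
  docs <- .check_corpus(docs)
  pdocs <- preprocess_corpus(docs, stemmer = model$config$stemmer,
                             stopwords = model$config$stopwords)
  lists <- .candidate_lists(model, pdocs, docs, external = external)
  out <- lapply(names(lists), function(id) {
    l <- lists[[id]]
    if (!nrow(l$features)) {
      pred <- .as_prediction_list(character(0), numeric(0), id)
    } else if (baseline == "nbr_freq") {
      pred <- .as_prediction_list(rownames(l$features),
                                  l$features[, "nbr_freq"], id)
    } else {
      s <- predict_lambdamart(model$ranker, l$features)
      pred <- .as_prediction_list(rownames(l$features), stats::plogis(s), id)
    }
    postprocess(pred, docs[[id]], model$vocab, model$config$prune,
                model$age_rules)
  })
  names(out) <- names(lists)
  out
}

#' Evaluate predictions against gold annotations
#'
#' @param predictions named list of `prediction_list` (from
#'   [mesh_predict()]) or of character vectors.
#' @param docs named list of annotated `mesh_document`.
#' @return a `mesh_eval_report` (see [evaluate_corpus()]).
#' @export
mesh_evaluate <- function(predictions, docs) {
  pred_ids <- lapply(predictions, function(p)
    if (is.data.frame(p)) p$descriptor_id else as.character(p))
  gold <- lapply(docs, `[[`, "gold_terms")
  names(gold) <- vapply(docs, `[[`, "", "doc_id")
  evaluate_corpus(pred_ids, gold)
}

#' Write predictions as TSV
#'
#' Columns: doc_id, rank, descriptor_id, preferred_name, score.
#'
#' @param predictions named list of `prediction_list`.
#' @param vocab a `mesh_vocabulary` (for preferred names).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_predictions_tsv <- function(predictions, vocab, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("doc_id\trank\tdescriptor_id\tpreferred_name\tscore", con)
  for (id in names(predictions)) {
    p <- predictions[[id]]
    if (!nrow(p)) next
    nm <- vapply(vocab$descriptors[p$descriptor_id], `[[`, "",
                 "preferred_name")
    writeLines(sprintf("%s\t%d\t%s\t%s\t%.17g", id, p$rank,
                       p$descriptor_id, nm, p$score), con)
  }
  invisible(path)
}

#' Write predictions as BioASQ-style JSON
#'
#' `{"documents": [{"pmid": ..., "labels": [...]}, ...]}`.
#'
#' @inheritParams write_predictions_tsv
#' @return `path`, invisibly.
#' @export
write_predictions_json <- function(predictions, path) {
  docs <- lapply(names(predictions), function(id)
    list(pmid = id, labels = I(predictions[[id]]$descriptor_id)))
  jsonlite::write_json(list(documents = docs), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

.load_vocab_any <- function(path) {
  if (grepl("\\.xml$", path, ignore.case = TRUE))
    load_vocabulary(path, "mesh-xml")
  else load_vocabulary(path, "tsv")
}

.load_corpus_any <- function(path) {
  if (grepl("\\.xml$", path, ignore.case = TRUE))
    read_corpus_medline_xml(path)
  else read_corpus_jsonl(path)
}

.config_from_file <- function(path, seed = NULL) {
  if (is.null(path)) return(mesh_config(seed = seed %||% 1))
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- mesh_config(seed = raw$seed %||% seed %||% 1)
  if (!is.null(raw$date_floor)) cfg$date_floor <- as.Date(raw$date_floor)
  for (nm in c("n_classifier_labels", "ibm_iters", "ibm_sample",
               "bg_sample", "n_rank_docs", "external", "stemmer"))
    if (!is.null(raw[[nm]])) cfg[[nm]] <- raw[[nm]]
  if (!is.null(raw$knn))
    cfg$knn <- do.call(knn_config, raw$knn)
  if (!is.null(raw$svm)) {
    args <- raw$svm; args$seed <- cfg$seed
    cfg$svm <- do.call(svm_config, args)
  }
  if (!is.null(raw$ranker))
    cfg$ranker <- utils::modifyList(cfg$ranker, raw$ranker)
  if (!is.null(raw$prune))
    cfg$prune <- do.call(pruning_config, raw$prune)
  cfg
}

#' Disk-artifact pipeline front end
#'
#' `mode = "train"` fits the full model from a corpus and vocabulary and
#' writes the model bundle (`model.rds`) plus interchange artifacts
#' (`ranker.json`, `classifiers/`, `translation.tsv.gz`,
#' `background.json`) into `out_dir`. `mode = "predict"` loads the bundle
#' and writes `predictions.tsv` and `predictions.json` for a corpus.
#' `mode = "evaluate"` compares `predictions.tsv` with the corpus gold
#' annotations and writes `report.json`. Missing upstream artifacts
#' produce errors naming the producing mode.
#'
#' @param corpus_path corpus file (JSONL or MEDLINE XML).
#' @param vocab_path vocabulary file (TSV dialect or descriptor XML).
#' @param mode `"train"`, `"predict"` or `"evaluate"`.
#' @param out_dir artifact directory.
#' @param config_path optional JSON configuration file.
#' @param seed seed override when no config file is given.
#' @param quiet suppress progress messages.
#' @return invisibly: the model (train), the predictions (predict) or
#'   the evaluation report (evaluate).
#' @export
run_pipeline <- function(corpus_path, vocab_path = NULL,
                         mode = c("train", "predict", "evaluate"),
                         out_dir = ".", config_path = NULL, seed = NULL,
                         quiet = FALSE) {
  mode <- match.arg(mode)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  model_path <- file.path(out_dir, "model.rds")
  pred_path <- file.path(out_dir, "predictions.tsv")
  if (mode == "train") {
    cfg <- .config_from_file(config_path, seed)
    vocab <- .load_vocab_any(vocab_path)
    corpus <- .load_corpus_any(corpus_path)
    model <- mesh_train(corpus, vocab, cfg, quiet = quiet)
    saveRDS(model, model_path)
    write_ranker(model$ranker, file.path(out_dir, "ranker.json"))
    write_classifiers(model$battery, file.path(out_dir, "classifiers"))
    write_translation_table(model$tt, file.path(out_dir, "translation.tsv.gz"))
    jsonlite::write_json(
      list(n_docs = model$bg$n_docs, avg_doc_len = model$bg$avg_doc_len,
           doc_freq = as.list(model$bg$doc_freq)),
      file.path(out_dir, "background.json"), auto_unbox = TRUE, digits = NA)
    return(invisible(model))
  }
  if (mode == "predict") {
    if (!file.exists(model_path))
      stop("missing artifact ", model_path,
           "; produce it with mode 'train' first")
    model <- readRDS(model_path)
    corpus <- .load_corpus_any(corpus_path)
    preds <- mesh_predict(model, corpus)
    write_predictions_tsv(preds, model$vocab, pred_path)
    write_predictions_json(preds, file.path(out_dir, "predictions.json"))
    return(invisible(preds))
  }
  # evaluate
  if (!file.exists(pred_path))
    stop("missing artifact ", pred_path,
         "; produce it with mode 'predict' first")
  tab <- utils::read.delim(pred_path, colClasses = "character")
  pred_ids <- split(tab$descriptor_id, tab$doc_id)
  corpus <- .load_corpus_any(corpus_path)
  gold <- lapply(corpus, `[[`, "gold_terms")
  pred_ids <- pred_ids[names(gold)]
  pred_ids[vapply(pred_ids, is.null, TRUE)] <- list(character())
  names(pred_ids) <- names(gold)
  report <- evaluate_corpus(pred_ids, gold)
  jsonlite::write_json(
    list(example = as.list(report$example), micro = as.list(report$micro),
         counts = as.list(report$counts)),
    file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  if (!quiet) print(report)
  invisible(report)
}
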