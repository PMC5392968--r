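# Candidate merging and feature extraction. Candidates come from three
# sources -- neighbour annotations, positively-classified labels, and an
# optional external recommender -- and are deduplicated with provenance
# flags OR-ed. Each candidate is described by a fixed feature schema
# consumed by the ranker.

#' Ranking feature schema
#'
#' Fixed, ordered feature names; the schema string is stored with trained
#' rankers and scoring with a mismatched schema is rejected.
#'
#' @return character vector of feature names.
#' @export
feature_schema <- function() {
  c("nbr_freq", "nbr_sim_sum", "unigram_overlap", "bigram_overlap",
    "translation_prob", "bm25", "trans_query_ll", "synonym_match",
    "classifier_score", "classifier_present", "external_flag")
}

#' @rdname feature_schema
#' @export
feature_schema_hash <- function() paste(feature_schema(), collapse = "|")

#' Merge the three candidate sources for one document
#'
#' Takes the union of (a) every unique descriptor annotated on the
#' neighbour documents, (b) every label whose classifier scores the
#' document positive, and (c) an optional external recommendation list;
#' deduplicates by descriptor id with source flags OR-ed. Classifier
#' scores are attached to every candidate whose label has a model,
#' whether or not the classifier fired, with a companion presence flag so
#' the ranker can distinguish "scored 0" from "unscored".
#'
#' @param pdoc the target document as a `processed_doc`.
#' @param neighbours data.frame from [knn_retrieve()].
#' @param neighbour_annotations named list doc_id -> gold descriptor ids
#'   (typically `index$annotations`).
#' @param models a `classifier_battery`, or `NULL`.
#' @param external character vector of externally recommended descriptor
#'   ids, or `NULL`.
#' @return data.frame with columns `descriptor_id`, `from_knn`,
#'   `from_classifier`, `from_external`, `classifier_score`,
#'   `classifier_present`, sorted by descriptor id. Empty (with a warning)
#'   when no source fires.
#' @export
generate_candidates <- function(pdoc, neighbours, neighbour_annotations,
                                models = NULL, external = NULL) {
  knn_terms <- unique(unlist(neighbour_annotations[neighbours$doc_id],
                             use.names = FALSE))
  scores <- numeric(0)
  if (!is.null(models) && length(models$models)) {
    scores <- vapply(models$models, predict_score, 0, pdoc = pdoc)
    names(scores) <- names(models$models)
  }
  cls_terms <- names(scores)[scores > 0]
  ext_terms <- unique(as.character(external %||% character()))
  ids <- sort(unique(c(knn_terms, cls_terms, ext_terms)))
  if (!length(ids)) {
    warning("no candidate source fired for document ",
            pdoc$doc_id %||% "<unnamed>")
    return(data.frame(descriptor_id = character(), from_knn = logical(),
                      from_classifier = logical(), from_external = logical(),
                      classifier_score = numeric(),
                      classifier_present = logical(),
                      stringsAsFactors = FALSE))
  }
  has_model <- ids %in% names(scores)
  data.frame(descriptor_id = ids,
             from_knn = ids %in% knn_terms,
             from_classifier = ids %in% cls_terms,
             from_external = ids %in% ext_terms,
             classifier_score = ifelse(has_model, scores[ids], 0),
             classifier_present = has_model,
             stringsAsFactors = FALSE)
}

# stemmed preferred-name tokens for every descriptor, computed once
.term_token_cache <- function(vocab, stemmer = "porter",
                              stopwords = default_stopwords()) {
  lapply(vocab$descriptors, function(d) {
    toks <- tokenize(d$preferred_name)
    toks <- toks[!toks %in% stopwords]
    if (stemmer == "porter") toks <- porter_stem(toks)
    toks
  })
}

.bigrams <- function(tokens) {
  if (length(tokens) < 2) return(character())
  paste(tokens[-length(tokens)], tokens[-1])
}

#' Feature vectors for a document's candidate list
#'
#' Computes the full [feature_schema()] matrix for all candidates of one
#' document: neighbourhood frequency (number of neighbours annotated with
#' the term) and similarity sum; fraction of the term name's stemmed
#' unigrams/bigrams present in title + abstract; translation probability
#' (product over name tokens of the per-token maximum `t(q|w)` over
#' document tokens, floored at 1e-9); BM25 and translation query
#' likelihood with the name as query; a case-folded synonym substring
#' match; the classifier score/presence pair; and the external flag.
#'
#' @param pdoc the target `processed_doc`.
#' @param doc the raw `mesh_document` (for synonym substring matching).
#' @param cands candidate data.frame from [generate_candidates()].
#' @param vocab a `mesh_vocabulary`.
#' @param neighbours data.frame from [knn_retrieve()].
#' @param neighbour_annotations named list doc_id -> descriptor ids.
#' @param tt a `translation_table`.
#' @param bg a [background_stats()] object.
#' @param term_tokens optional precomputed stemmed name-token cache (from
#'   the internal cache builder); computed on the fly if `NULL`.
#' @param stemmer,stopwords preprocessing settings (must match the index).
#' @return numeric matrix, one row per candidate (rownames = descriptor
#'   ids), columns = [feature_schema()].
#' @export
candidate_features <- function(pdoc, doc, cands, vocab, neighbours,
                               neighbour_annotations, tt, bg,
                               term_tokens = NULL, stemmer = "porter",
                               stopwords = default_stopwords()) {
  .check_ids(vocab, cands$descriptor_id)
  schema <- feature_schema()
  out <- matrix(0, nrow = nrow(cands), ncol = length(schema),
                dimnames = list(cands$descriptor_id, schema))
  if (!nrow(cands)) return(out)
  if (is.null(term_tokens))
    term_tokens <- .term_token_cache(vocab, stemmer, stopwords)
  doc_tok_set <- unique(pdoc$tokens)
  doc_bigrams <- unique(.bigrams(pdoc$tokens))
  raw_text <- tolower(paste(doc$title, doc$abstract))
  nbr_terms <- lapply(neighbours$doc_id, function(id)
    neighbour_annotations[[id]] %||% character())

  for (r in seq_len(nrow(cands))) {
    id <- cands$descriptor_id[r]
    ntoks <- term_tokens[[id]]
    in_nbr <- vapply(nbr_terms, function(tt2) id %in% tt2, TRUE)
    out[r, "nbr_freq"] <- sum(in_nbr)
    out[r, "nbr_sim_sum"] <- sum(neighbours$similarity[in_nbr])
    if (length(ntoks)) {
      out[r, "unigram_overlap"] <- mean(ntoks %in% doc_tok_set)
      nbg <- .bigrams(ntoks)
      if (length(nbg))
        out[r, "bigram_overlap"] <- mean(nbg %in% doc_bigrams)
      tp <- vapply(ntoks, function(q) {
        if (!(q %in% tt$term_vocab)) return(0)
        known <- doc_tok_set[doc_tok_set %in% tt$doc_vocab]
        if (!length(known)) return(0)
        max(tt$t[q, known])
      }, 0)
      out[r, "translation_prob"] <- prod(pmax(tp, 1e-9))
      out[r, "bm25"] <- bm25_score(ntoks, pdoc, bg)
      ll <- translation_query_likelihood(ntoks, pdoc, tt, bg)
      out[r, "trans_query_ll"] <- if (is.finite(ll)) ll else -1e6
    }
    syns <- vocab$descriptors[[id]]$synonyms
    out[r, "synonym_match"] <-
      as.numeric(length(syns) > 0 &&
                 any(vapply(tolower(syns), grepl, TRUE, x = raw_text,
                            fixed = TRUE)))
    out[r, "classifier_score"] <- cands$classifier_score[r]
    out[r, "classifier_present"] <- as.numeric(cands$classifier_present[r])
    out[r, "external_flag"] <- as.numeric(cands$from_external[r])
  }
  out
}

#' Feature vector of a single candidate
#'
#' Convenience wrapper around [candidate_features()] for one candidate.
#'
#' @param pdoc,doc,vocab,neighbours,neighbour_annotations,tt,bg see
#'   [candidate_features()].
#' @param cand one-row candidate data.frame (or a descriptor id, in which
#'   case provenance flags are taken as all-FALSE with no classifier).
#' @return named numeric vector following [feature_schema()].
#' @export
extract_features <- function(pdoc, doc, cand, vocab, neighbours,
                             neighbour_annotations, tt, bg) {
  if (is.character(cand))
    cand <- data.frame(descriptor_id = cand, from_knn = FALSE,
                       from_classifier = FALSE, from_external = FALSE,
                       classifier_score = 0, classifier_present = FALSE,
                       stringsAsFactors = FALSE)
  candidate_features(pdoc, doc, cand, vocab, neighbours,
                     neighbour_annotations, tt, bg)[1, ]
}

#' Write candidate/feature training lists as TSV
#'
#' The ranker's training exchange format: one row per (document,
#' candidate) with the relevance label and the feature columns.
#'
#' @param lists named list (by doc_id) of `list(features = <matrix>,
#'   labels = <0/1 vector>)`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_feature_lists <- function(lists, path) {
  schema <- feature_schema()
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("doc_id", "descriptor_id", "label", schema),
                   collapse = "\t"), con)
  for (doc_id in names(lists)) {
    l <- lists[[doc_id]]
    if (!nrow(l$features)) next
    writeLines(paste(doc_id, rownames(l$features), l$labels,
                     apply(l$features, 1, function(v)
                       paste(sprintf("%.17g", v), collapse = "\t")),
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Read candidate/feature training lists written by [write_feature_lists()]
#'
#' @param path file path.
#' @return named list of `list(features, labels)` keyed by doc_id.
#' @export
read_feature_lists <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  schema <- feature_schema()
  if (!all(schema %in% names(tab)))
    stop("feature TSV ", path, " does not match the feature schema")
  split_idx <- split(seq_len(nrow(tab)), tab$doc_id)
  lapply(split_idx, function(rows) {
    f <- as.matrix(tab[rows, schema, drop = FALSE])
    rownames(f) <- tab$descriptor_id[rows]
    list(features = f, labels = tab$label[rows])
  })
}
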