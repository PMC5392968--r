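# Synthetic vocabulary and corpus generator. Produces a balanced toy
# descriptor tree plus documents whose text is a mixture of their labels'
# signature words and background noise, so that the central assumption of
# neighbour-based indexing -- documents similar in content share similar
# annotations -- holds by construction, classifiers and overlap/translation
# features have learnable signal, and abstracts can carry explicit age
# phrases consistent with their age check tags.

#' Synthetic fixture specification
#'
#' @param depth,branching shape of the balanced descriptor tree; the
#'   number of labels is `branching + branching^2 + ... + branching^depth`
#'   (39 for the default 3/3).
#' @param n_docs number of documents (default 2000).
#' @param vocab_size size of the signature/background word pool.
#' @param words_per_label signature words per label.
#' @param mean_labels target mean number of labels per document; drawn
#'   from a truncated negative binomial. The default 12.7 mirrors the
#'   observed mean annotation count per article in large indexing
#'   corpora.
#' @param nb_size negative binomial size (dispersion) parameter.
#' @param noise_rate fraction of abstract tokens drawn from the
#'   background pool instead of label signatures.
#' @param n_age_tags number of leaf descriptors turned into age check
#'   tags (0 disables age phrases entirely).
#' @param check_tag_fraction fraction of descriptors flagged as check
#'   tags (age tags count towards it).
#' @param title_len,abstract_len token counts for titles and abstracts
#'   (abstract length is uniform between the two values given).
#' @param seed generator seed.
#' @return a `fixture_spec` list.
#' @export
fixture_spec <- function(depth = 3, branching = 3, n_docs = 2000,
                         vocab_size = 1500, words_per_label = 6,
                         mean_labels = 12.7, nb_size = 8, noise_rate = 0.2,
                         n_age_tags = 6, check_tag_fraction = 0.15,
                         title_len = 6, abstract_len = c(60, 100),
                         seed = 42) {
  stopifnot(depth >= 1, branching >= 1, n_docs >= 1, noise_rate >= 0,
            noise_rate <= 1, words_per_label >= 1, mean_labels > 0)
  n_labels <- sum(branching^seq_len(depth))
  stopifnot(vocab_size >= n_labels * words_per_label + 50)
  structure(list(depth = depth, branching = branching, n_docs = n_docs,
                 vocab_size = vocab_size, words_per_label = words_per_label,
                 mean_labels = mean_labels, nb_size = nb_size,
                 noise_rate = noise_rate, n_age_tags = n_age_tags,
                 check_tag_fraction = check_tag_fraction,
                 title_len = title_len, abstract_len = abstract_len,
                 n_labels = n_labels, seed = as.integer(seed)),
            class = "fixture_spec")
}

.AGE_TAG_NAMES <- c("Infant", "Child, Preschool", "Child", "Adolescent",
                    "Adult", "Aged")
# phrase ranges chosen inside each tag's detection range
.AGE_PHRASES <- list(
  "Infant" = list(lo = 2, hi = 20, unit = "months"),
  "Child, Preschool" = list(lo = 2, hi = 5, unit = "years"),
  "Child" = list(lo = 6, hi = 12, unit = "years"),
  "Adolescent" = list(lo = 13, hi = 18, unit = "years"),
  "Adult" = list(lo = 25, hi = 44, unit = "years"),
  "Aged" = list(lo = 66, hi = 79, unit = "years"))

# pronounceable pseudo-words (3 consonant-vowel syllables), unique, no
# stop words
.make_words <- function(n) {
  cons <- c("b", "d", "f", "g", "k", "l", "m", "n", "p", "r", "s", "t",
            "v", "z")
  vow <- c("a", "e", "i", "o", "u")
  out <- character(0)
  while (length(out) < n) {
    need <- n - length(out)
    w <- vapply(seq_len(need * 2), function(i)
      paste0(sample(cons, 3, TRUE), sample(vow, 3, TRUE), collapse = ""),
      "")
    w <- paste0(substr(w, 1, 1), substr(w, 4, 4), substr(w, 2, 2),
                substr(w, 5, 5), substr(w, 3, 3), substr(w, 6, 6))
    out <- unique(c(out, setdiff(w, .STOPWORDS)))
  }
  out[seq_len(n)]
}

# deterministic word layout shared by make_vocabulary and make_corpus
.fixture_words <- function(spec) {
  set.seed(spec$seed)
  pool <- .make_words(spec$vocab_size)
  n_sig <- spec$n_labels * spec$words_per_label
  signatures <- split(pool[seq_len(n_sig)],
                      rep(seq_len(spec$n_labels), each = spec$words_per_label))
  background <- pool[(n_sig + 1):spec$vocab_size]
  list(signatures = signatures, background = background)
}

.fixture_ids <- function(spec) sprintf("D%03d", seq_len(spec$n_labels))

# tree numbers assigned breadth-first over the balanced tree
.fixture_trees <- function(spec) {
  trees <- as.character(seq_len(spec$branching))
  level <- trees
  for (d in seq_len(spec$depth - 1)) {
    level <- unlist(lapply(level, function(p)
      paste(p, seq_len(spec$branching), sep = ".")))
    trees <- c(trees, level)
  }
  trees
}

#' Generate a toy vocabulary
#'
#' A balanced descriptor tree with generated preferred names built from
#' each label's signature words, 0-3 synonyms per descriptor (drawn from
#' the label's remaining signature words), and a flagged check-tag subset
#' whose first members are age tags carrying the standard NLM age-group
#' names.
#'
#' @param spec a [fixture_spec()].
#' @return a `mesh_vocabulary`.
#' @export
make_vocabulary <- function(spec) {
  words <- .fixture_words(spec)
  ids <- .fixture_ids(spec)
  trees <- .fixture_trees(spec)
  n <- spec$n_labels
  n_age <- min(spec$n_age_tags, length(.AGE_TAG_NAMES))
  # age tags take the last descriptors (leaves of the deepest level)
  age_idx <- if (n_age > 0) seq(n - n_age + 1, n) else integer(0)
  n_check <- max(n_age, ceiling(spec$check_tag_fraction * n))
  check_idx <- unique(c(age_idx, seq(n, by = -1,
                                     length.out = min(n_check, n))))
  set.seed(spec$seed + 1L)
  desc <- lapply(seq_len(n), function(i) {
    sig <- words$signatures[[i]]
    nm <- if (i %in% age_idx)
      .AGE_TAG_NAMES[match(i, age_idx)]
    else
      paste(toupper(substr(sig[1:2], 1, 1)),
            substr(sig[1:2], 2, nchar(sig[1:2])), sep = "", collapse = " ")
    n_syn <- sample(0:3, 1)
    syn <- if (n_syn > 0)
      sig[seq(3, length.out = min(n_syn, length(sig) - 2))] else character()
    new_descriptor(ids[i], nm, synonyms = syn, tree_numbers = trees[i],
                   is_check_tag = i %in% check_idx)
  })
  new_vocabulary(desc)
}

#' Generate a synthetic corpus
#'
#' Each document draws a label count from a truncated negative binomial
#' (mean `spec$mean_labels`), samples that many labels with mildly skewed
#' popularity weights, and builds its title and abstract as a mixture of
#' the labels' signature words with background words at `noise_rate`.
#' Documents annotated with an age check tag embed a matching explicit
#' age phrase ("aged N years"/"aged N months") in the abstract.
#' Annotation dates are uniform over 2009-01-01..2014-03-31.
#'
#' @param spec a [fixture_spec()].
#' @param vocab the vocabulary from [make_vocabulary()] (same spec).
#' @return named list of `mesh_document`.
#' @export
make_corpus <- function(spec, vocab) {
  words <- .fixture_words(spec)
  ids <- .fixture_ids(spec)
  n <- spec$n_labels
  weights <- 1 / sqrt(seq_len(n))
  date_range <- as.integer(as.Date(c("2009-01-01", "2014-03-31")))
  age_names <- vapply(vocab$descriptors[ids], `[[`, "", "preferred_name")
  set.seed(spec$seed + 2L)
  docs <- lapply(seq_len(spec$n_docs), function(di) {
    L <- min(n, max(1L, stats::rnbinom(1, size = spec$nb_size,
                                       mu = spec$mean_labels)))
    lab_idx <- sample.int(n, L, prob = weights)
    sig_pool <- unlist(words$signatures[lab_idx], use.names = FALSE)
    title <- sample(sig_pool, spec$title_len, replace = TRUE)
    n_ab <- sample(spec$abstract_len[1]:spec$abstract_len[2], 1)
    is_noise <- stats::runif(n_ab) < spec$noise_rate
    ab <- character(n_ab)
    ab[is_noise] <- sample(words$background, sum(is_noise), replace = TRUE)
    ab[!is_noise] <- sample(sig_pool, sum(!is_noise), replace = TRUE)
    abstract <- paste(ab, collapse = " ")
    for (li in lab_idx) {
      ph <- .AGE_PHRASES[[age_names[li]]]
      if (!is.null(ph)) {
        age <- sample(ph$lo:ph$hi, 1)
        abstract <- paste0(abstract, " Participants aged ", age, " ",
                           ph$unit, " were enrolled.")
      }
    }
    new_document(sprintf("doc%05d", di),
                 title = paste(title, collapse = " "),
                 abstract = abstract,
                 gold_terms = ids[sort(lab_idx)],
                 annotation_date = as.Date(
                   sample(date_range[1]:date_range[2], 1), origin = "1970-01-01"))
  })
  .check_corpus(docs)
}

#' Rule-based pseudo external recommender
#'
#' A deterministic stand-in for a production recommendation service used
#' to exercise the external-candidate channel: descriptors are scored by
#' the number of their stemmed name tokens present in the document and
#' the top `m` with a positive score are returned (ties broken by id).
#'
#' @param pdoc a `processed_doc`.
#' @param vocab a `mesh_vocabulary`.
#' @param term_tokens optional precomputed stemmed-name-token cache.
#' @param m maximum number of recommendations.
#' @return character vector of descriptor ids.
#' @export
external_recommend <- function(pdoc, vocab, term_tokens = NULL, m = 10) {
  if (is.null(term_tokens)) term_tokens <- .term_token_cache(vocab)
  toks <- unique(pdoc$tokens)
  score <- vapply(term_tokens, function(nt) sum(nt %in% toks), 0)
  ids <- names(score)[score > 0]
  score <- score[score > 0]
  ids[order(-score, ids)][seq_len(min(m, length(ids)))]
}

#' Write a complete synthetic fixture to disk
#'
#' Emits `vocabulary.tsv` (TSV dialect), `corpus.jsonl` and
#' `stats.json` (generation summary) into `dir`.
#'
#' @param dir output directory (created if needed).
#' @param spec a [fixture_spec()].
#' @return invisibly, a list with the vocabulary and corpus.
#' @export
write_fixture <- function(dir, spec = fixture_spec()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vocab <- make_vocabulary(spec)
  corpus <- make_corpus(spec, vocab)
  write_vocabulary_tsv(vocab, file.path(dir, "vocabulary.tsv"))
  write_corpus_jsonl(corpus, file.path(dir, "corpus.jsonl"))
  mean_labels <- mean(vapply(corpus, function(d) length(d$gold_terms), 0))
  jsonlite::write_json(
    list(n_labels = spec$n_labels, n_docs = spec$n_docs,
         mean_labels_per_doc = mean_labels, seed = spec$seed),
    file.path(dir, "stats.json"), auto_unbox = TRUE, digits = NA)
  invisible(list(vocab = vocab, corpus = corpus))
}
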