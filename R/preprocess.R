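# Text preprocessing: tokenization, stop-word removal, Porter stemming.
# The stemmer is the classic Porter (1980) algorithm, written out in full
# because suffix conflation must match between document text and descriptor
# names; it is deterministic and oracle-tested against the published
# example conflations.

#' Default English stop-word list
#'
#' A standard list of high-frequency function words removed before
#' indexing and similarity computation.
#'
#' @return character vector of lowercase stop words.
#' @export
default_stopwords <- function() .STOPWORDS

.STOPWORDS <- c(
  "a", "about", "above", "after", "again", "against", "all", "also", "am",
  "an", "and", "any", "are", "as", "at", "be", "because", "been", "before",
  "being", "below", "between", "both", "but", "by", "can", "cannot", "could",
  "did", "do", "does", "doing", "down", "during", "each", "few", "for",
  "from", "further", "had", "has", "have", "having", "he", "her", "here",
  "hers", "him", "his", "how", "i", "if", "in", "into", "is", "it", "its",
  "itself", "just", "may", "me", "might", "more", "most", "must", "my", "no",
  "nor", "not", "now", "of", "off", "on", "once", "only", "or", "other",
  "our", "ours", "out", "over", "own", "per", "same", "she", "should", "so",
  "some", "such", "than", "that", "the", "their", "theirs", "them", "then",
  "there", "these", "they", "this", "those", "through", "to", "too", "under",
  "until", "up", "upon", "very", "was", "we", "were", "what", "when",
  "where", "which", "while", "who", "whom", "why", "will", "with", "within",
  "without", "would", "you", "your", "yours")

#' Tokenize text
#'
#' Case-folds and splits on any non-alphanumeric character.
#'
#' @param text character vector.
#' @return character vector of lowercase tokens (text concatenated).
#' @export
tokenize <- function(text) {
  text <- tolower(paste(text, collapse = " "))
  toks <- regmatches(text, gregexpr("[a-z0-9]+", text))[[1]]
  toks[nzchar(toks)]
}

# ---- Porter stemmer ---------------------------------------------------------

# consonant/vowel pattern: y is a vowel when preceded by a consonant
.porter_pat <- function(chars) {
  n <- length(chars)
  isv <- logical(n)
  for (i in seq_len(n)) {
    ch <- chars[i]
    isv[i] <- ch %in% c("a", "e", "i", "o", "u") ||
      (ch == "y" && i > 1L && !isv[i - 1L])
  }
  isv
}

# measure m: number of vowel->consonant transitions in [C](VC)^m[V]
.porter_m <- function(stem) {
  if (!nchar(stem)) return(0L)
  isv <- .porter_pat(strsplit(stem, "", fixed = TRUE)[[1]])
  runs <- rle(isv)$values
  sum(runs[-length(runs)] & !runs[-1])  # v-run followed by c-run
}

.has_vowel <- function(stem) {
  if (!nchar(stem)) return(FALSE)
  any(.porter_pat(strsplit(stem, "", fixed = TRUE)[[1]]))
}

# *d: ends with a double consonant
.ends_double_c <- function(w) {
  n <- nchar(w)
  if (n < 2) return(FALSE)
  a <- substr(w, n - 1, n - 1); b <- substr(w, n, n)
  if (a != b) return(FALSE)
  isv <- .porter_pat(strsplit(w, "", fixed = TRUE)[[1]])
  !isv[n]
}

# *o: ends cvc where the final consonant is not w, x or y
.ends_cvc <- function(w) {
  n <- nchar(w)
  if (n < 3) return(FALSE)
  isv <- .porter_pat(strsplit(w, "", fixed = TRUE)[[1]])
  last <- substr(w, n, n)
  !isv[n - 2] && isv[n - 1] && !isv[n] && !(last %in% c("w", "x", "y"))
}

.chop <- function(w, k) substr(w, 1, nchar(w) - k)
.ends <- function(w, s) {
  nchar(w) > nchar(s) && endsWith(w, s)  # suffix must leave a non-empty stem
}

# rule tables: suffix -> replacement; longest suffix matched first, and once
# a suffix matches, its condition decides -- shorter suffixes are not tried
.RULES2 <- list(
  c("ational", "ate"), c("ization", "ize"), c("iveness", "ive"),
  c("fulness", "ful"), c("ousness", "ous"), c("tional", "tion"),
  c("biliti", "ble"), c("entli", "ent"), c("ousli", "ous"),
  c("ation", "ate"), c("alism", "al"), c("aliti", "al"), c("iviti", "ive"),
  c("enci", "ence"), c("anci", "ance"), c("izer", "ize"), c("abli", "able"),
  c("alli", "al"), c("ator", "ate"), c("logi", "log"), c("eli", "e"))
.RULES3 <- list(
  c("icate", "ic"), c("ative", ""), c("alize", "al"), c("iciti", "ic"),
  c("ical", "ic"), c("ful", ""), c("ness", ""))
.SUFF4 <- c("ement", "ance", "ence", "able", "ible", "ment", "ant", "ent",
            "ism", "ate", "iti", "ous", "ive", "ize", "ion", "al", "er",
            "ic", "ou")

.porter_word <- function(w) {
  if (nchar(w) < 3 || grepl("[^a-z]", w)) return(w)

  # step 1a
  if (endsWith(w, "sses")) w <- .chop(w, 2)
  else if (endsWith(w, "ies")) w <- .chop(w, 2)
  else if (!endsWith(w, "ss") && endsWith(w, "s")) w <- .chop(w, 1)

  # step 1b
  fixup <- FALSE
  if (.ends(w, "eed")) {
    if (.porter_m(.chop(w, 3)) > 0) w <- .chop(w, 1)
  } else if (.ends(w, "ed") && .has_vowel(.chop(w, 2))) {
    w <- .chop(w, 2); fixup <- TRUE
  } else if (.ends(w, "ing") && .has_vowel(.chop(w, 3))) {
    w <- .chop(w, 3); fixup <- TRUE
  }
  if (fixup) {
    if (endsWith(w, "at") || endsWith(w, "bl") || endsWith(w, "iz"))
      w <- paste0(w, "e")
    else if (.ends_double_c(w) &&
             !substr(w, nchar(w), nchar(w)) %in% c("l", "s", "z"))
      w <- .chop(w, 1)
    else if (.porter_m(w) == 1 && .ends_cvc(w))
      w <- paste0(w, "e")
  }

  # step 1c
  if (.ends(w, "y") && .has_vowel(.chop(w, 1)))
    w <- paste0(.chop(w, 1), "i")

  # step 2
  for (rule in .RULES2) {
    if (.ends(w, rule[1])) {
      stem <- .chop(w, nchar(rule[1]))
      if (.porter_m(stem) > 0) w <- paste0(stem, rule[2])
      break
    }
  }

  # step 3
  for (rule in .RULES3) {
    if (.ends(w, rule[1])) {
      stem <- .chop(w, nchar(rule[1]))
      if (.porter_m(stem) > 0) w <- paste0(stem, rule[2])
      break
    }
  }

  # step 4
  for (suf in .SUFF4) {
    if (.ends(w, suf)) {
      stem <- .chop(w, nchar(suf))
      ok <- .porter_m(stem) > 1
      if (ok && suf == "ion")
        ok <- substr(stem, nchar(stem), nchar(stem)) %in% c("s", "t")
      if (ok) w <- stem
      break
    }
  }

  # step 5a
  if (endsWith(w, "e")) {
    stem <- .chop(w, 1)
    m <- .porter_m(stem)
    if (m > 1 || (m == 1 && !.ends_cvc(stem))) w <- stem
  }
  # step 5b
  if (.porter_m(w) > 1 && .ends_double_c(w) && endsWith(w, "l"))
    w <- .chop(w, 1)

  w
}

#' Porter stemmer
#'
#' The Porter (1980) suffix-stripping algorithm, vectorized over words.
#' Words shorter than three characters or containing non-letters are
#' returned unchanged.
#'
#' @param words character vector of lowercase words.
#' @return character vector of stems.
#' @export
porter_stem <- function(words) {
  if (!length(words)) return(character())
  uw <- unique(words)
  stems <- vapply(uw, .porter_word, "", USE.NAMES = FALSE)
  stems[match(words, uw)]
}

#' Preprocess a document into tokens
#'
#' Case-folds, tokenizes, removes stop words and stems title + abstract
#' (in that order). Gold annotations never contribute tokens.
#'
#' @param d a `mesh_document`, or a character vector of raw text.
#' @param stemmer `"porter"` or `"none"`.
#' @param stopwords character vector of stop words to remove (matched
#'   before stemming).
#' @return an object of class `processed_doc`: `doc_id`, `tokens` (ordered
#'   stemmed tokens), `tf` (named counts) and `length` (token count).
#' @export
preprocess <- function(d, stemmer = c("porter", "none"),
                       stopwords = default_stopwords()) {
  stemmer <- match.arg(stemmer)
  if (inherits(d, "mesh_document")) {
    txt <- c(d$title, d$abstract)
    id <- d$doc_id
  } else {
    txt <- as.character(d)
    id <- NA_character_
  }
  toks <- tokenize(txt)
  toks <- toks[!toks %in% stopwords]
  if (stemmer == "porter") toks <- porter_stem(toks)
  tf <- if (length(toks)) table(toks) else integer()
  structure(list(doc_id = id, tokens = toks,
                 tf = stats::setNames(as.integer(tf), names(tf)),
                 length = length(toks)),
            class = "processed_doc")
}

#' Preprocess every document of a corpus
#'
#' @param corpus list of `mesh_document` objects.
#' @inheritParams preprocess
#' @return named list of `processed_doc`, keyed by doc_id.
#' @export
preprocess_corpus <- function(corpus, stemmer = c("porter", "none"),
                              stopwords = default_stopwords()) {
  stemmer <- match.arg(stemmer)
  out <- lapply(corpus, preprocess, stemmer = stemmer, stopwords = stopwords)
  names(out) <- vapply(corpus, `[[`, "", "doc_id")
  out
}
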