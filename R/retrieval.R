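# Retrieval models used as ranking features: IBM Model 1 term translation
# (EM-trained, conditioning term tokens on document tokens), corpus
# background statistics, Okapi BM25, and a translation-based query
# likelihood with Jelinek-Mercer smoothing. A term's preferred name plays
# the role of the query; the title + abstract plays the document.

#' Train an IBM Model 1 translation table
#'
#' Standard IBM Model 1 expectation-maximization from uniform
#' initialization over parallel pairs of (term tokens, document tokens).
#' Titles and abstracts act as the source language and descriptor names as
#' the target language, so the table stores `t(q | w)`: the probability of
#' term token q given document token w, normalized over q for each w. The
#' training-data log-likelihood is non-decreasing across iterations and
#' the normalization invariant is asserted after every iteration.
#'
#' @param pairs list of `list(term = <character tokens>, doc = <character
#'   tokens>)` pairs.
#' @param iters maximum EM iterations.
#' @param tol stop early when the log-likelihood gain drops below `tol`.
#' @return object of class `translation_table`: probability matrix `t`
#'   (term tokens by doc tokens, columns sum to 1), vocabularies, and the
#'   log-likelihood trace `ll`.
#' @export
train_ibm1 <- function(pairs, iters = 20, tol = 1e-4) {
  if (!length(pairs)) stop("empty pair list")
  pairs <- lapply(pairs, function(p) {
    list(q = table(as.character(p$term)), w = table(as.character(p$doc)))
  })
  pairs <- pairs[vapply(pairs, function(p) length(p$q) > 0 && length(p$w) > 0,
                        TRUE)]
  if (!length(pairs)) stop("no non-empty pairs to train on")
  term_vocab <- sort(unique(unlist(lapply(pairs, function(p) names(p$q)))))
  doc_vocab <- sort(unique(unlist(lapply(pairs, function(p) names(p$w)))))
  nt <- length(term_vocab); nd <- length(doc_vocab)
  tmat <- matrix(1 / nt, nrow = nt, ncol = nd,
                 dimnames = list(term_vocab, doc_vocab))
  # precompute index/count forms
  prep <- lapply(pairs, function(p) {
    list(qi = match(names(p$q), term_vocab), qc = as.numeric(p$q),
         wi = match(names(p$w), doc_vocab), wc = as.numeric(p$w))
  })
  ll <- numeric(0)
  for (it in seq_len(iters)) {
    counts <- matrix(0, nrow = nt, ncol = nd,
                     dimnames = list(term_vocab, doc_vocab))
    cur_ll <- 0
    for (p in prep) {
      sub <- tmat[p$qi, p$wi, drop = FALSE]        # |q| x |w|
      wl <- sum(p$wc)
      denom <- as.numeric(sub %*% p$wc)            # sum_w c(w) t(q|w)
      cur_ll <- cur_ll + sum(p$qc * (log(denom) - log(wl)))
      post <- sub * rep(p$wc, each = length(p$qi)) / denom  # P(w | q)
      counts[p$qi, p$wi] <- counts[p$qi, p$wi] + post * p$qc
    }
    ll <- c(ll, cur_ll)
    csum <- colSums(counts)
    csum[csum == 0] <- 1
    tmat <- sweep(counts, 2, csum, "/")
    stopifnot(all(abs(colSums(tmat) - 1) < 1e-9 | colSums(tmat) == 0))
    if (it >= 2 && (ll[it] - ll[it - 1]) < tol) break
  }
  structure(list(t = tmat, term_vocab = term_vocab, doc_vocab = doc_vocab,
                 ll = ll),
            class = "translation_table")
}

#' @export
print.translation_table <- function(x, ...) {
  cat("translation_table:", length(x$term_vocab), "term tokens x",
      length(x$doc_vocab), "doc tokens,", length(x$ll), "EM iterations\n")
  invisible(x)
}

#' Translation probability lookup
#'
#' @param tt a `translation_table`.
#' @param q term token(s).
#' @param w document token.
#' @return `t(q | w)`; 0 for unseen tokens.
#' @export
t_prob <- function(tt, q, w) {
  if (!(w %in% tt$doc_vocab)) return(rep(0, length(q)))
  out <- rep(0, length(q))
  known <- q %in% tt$term_vocab
  out[known] <- tt$t[q[known], w]
  out
}

#' Background collection statistics
#'
#' Document frequencies, collection term counts, document count and
#' average document length over (a sample of) a corpus, for BM25 and the
#' background unigram model. Mirrors the reference setup of estimating
#' these statistics from a sample of recent documents (~60,000 in the
#' original setting) rather than the whole collection.
#'
#' @param pdocs named list of `processed_doc`.
#' @param sample_n optional cap on the number of documents used (seeded).
#' @param seed sampling seed.
#' @return object of class `background_stats`: `doc_freq`, `cf`
#'   (collection counts), `n_docs`, `avg_doc_len`, `total_tokens`.
#' @export
background_stats <- function(pdocs, sample_n = NULL, seed = 1) {
  if (!length(pdocs)) stop("no documents for background statistics")
  if (!is.null(sample_n) && length(pdocs) > sample_n) {
    set.seed(seed)
    pdocs <- pdocs[sort(sample(seq_along(pdocs), sample_n))]
  }
  tok <- unlist(lapply(pdocs, function(p) names(p$tf)), use.names = FALSE)
  cnt <- unlist(lapply(pdocs, function(p) as.numeric(p$tf)), use.names = FALSE)
  cf <- tapply(cnt, tok, sum)
  df <- tapply(rep(1, length(tok)), tok, sum)
  structure(list(doc_freq = stats::setNames(as.integer(df), names(df)),
                 cf = stats::setNames(as.numeric(cf), names(cf)),
                 n_docs = length(pdocs),
                 avg_doc_len = mean(vapply(pdocs, `[[`, 0L, "length")),
                 total_tokens = sum(cnt)),
            class = "background_stats")
}

.bg_df <- function(bg, tokens) {
  out <- bg$doc_freq[tokens]
  out[is.na(out)] <- 0L
  unname(out)
}

# smoothed background unigram probability
.bg_prob <- function(bg, tokens) {
  cf <- bg$cf[tokens]
  cf[is.na(cf)] <- 0
  v <- length(bg$cf) + 1
  unname((cf + 0.5) / (bg$total_tokens + 0.5 * v))
}

#' Okapi BM25 score of a term-name query against a document
#'
#' `sum_q idf(q) * tf(q,d) (k1 + 1) / (tf(q,d) + k1 (1 - b + b len/avglen))`
#' with `idf = ln((n - df + 0.5) / (df + 0.5) + 1)`. Query tokens absent
#' from the document contribute 0; unseen tokens use the df = 0 branch.
#'
#' @param query_tokens character vector (stemmed term-name tokens).
#' @param pdoc a `processed_doc`.
#' @param bg a [background_stats()] object.
#' @param k1,b BM25 parameters (1.2 and 0.75 by default).
#' @return numeric score (non-negative).
#' @export
bm25_score <- function(query_tokens, pdoc, bg, k1 = 1.2, b = 0.75) {
  if (!length(query_tokens) || pdoc$length == 0) return(0)
  tf <- pdoc$tf[query_tokens]
  tf[is.na(tf)] <- 0
  tf <- unname(as.numeric(tf))
  df <- .bg_df(bg, query_tokens)
  idf <- log((bg$n_docs - df + 0.5) / (df + 0.5) + 1)
  denom <- tf + k1 * (1 - b + b * pdoc$length / bg$avg_doc_len)
  sum(idf * tf * (k1 + 1) / denom)
}

#' Translation-based query log-likelihood
#'
#' `sum_q log( mix * sum_w t(q|w) p_ml(w|doc) + (1 - mix) * p_bg(q) )`
#' where `p_ml` is the maximum-likelihood document unigram model, `p_bg`
#' the smoothed background model, and the mixture is Jelinek-Mercer with
#' weight `mix` on the translation channel.
#'
#' @param query_tokens character vector (stemmed term-name tokens).
#' @param pdoc a `processed_doc`.
#' @param tt a `translation_table`.
#' @param bg a [background_stats()] object.
#' @param mix mixture weight in `[0, 1]` (default 0.5).
#' @return log-likelihood (<= 0 in practice); `-Inf` with attribute
#'   `"degenerate"` when a token has zero probability under a pure
#'   translation model (`mix = 1`).
#' @export
translation_query_likelihood <- function(query_tokens, pdoc, tt, bg,
                                         mix = 0.5) {
  stopifnot(mix >= 0, mix <= 1)
  if (!length(query_tokens)) return(0)
  p_bg <- .bg_prob(bg, query_tokens)
  doc_toks <- names(pdoc$tf)
  p_ml <- if (pdoc$length > 0) as.numeric(pdoc$tf) / pdoc$length else numeric(0)
  trans <- vapply(query_tokens, function(q) {
    if (!length(doc_toks) || !(q %in% tt$term_vocab)) return(0)
    known <- doc_toks %in% tt$doc_vocab
    if (!any(known)) return(0)
    sum(tt$t[q, doc_toks[known]] * p_ml[known])
  }, 0)
  p <- mix * trans + (1 - mix) * p_bg
  if (any(p == 0)) {
    out <- -Inf
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  sum(log(p))
}

#' Persist a translation table as gzip TSV
#'
#' Columns `term_token`, `doc_token`, `probability`; zero entries omitted.
#'
#' @param tt a `translation_table`.
#' @param path output path (`.tsv.gz`).
#' @return `path`, invisibly.
#' @export
write_translation_table <- function(tt, path) {
  nz <- which(tt$t > 0, arr.ind = TRUE)
  con <- gzfile(path, "w")
  on.exit(close(con))
  writeLines(c("term_token\tdoc_token\tprobability",
               sprintf("%s\t%s\t%.17g",
                       tt$term_vocab[nz[, 1]], tt$doc_vocab[nz[, 2]],
                       tt$t[nz])), con)
  invisible(path)
}

#' Load a translation table written by [write_translation_table()]
#'
#' @param path file path.
#' @return a `translation_table` (log-likelihood trace not preserved).
#' @export
read_translation_table <- function(path) {
  tab <- utils::read.delim(gzfile(path),
                           colClasses = c("character", "character", "numeric"))
  term_vocab <- sort(unique(tab$term_token))
  doc_vocab <- sort(unique(tab$doc_token))
  tmat <- matrix(0, length(term_vocab), length(doc_vocab),
                 dimnames = list(term_vocab, doc_vocab))
  tmat[cbind(match(tab$term_token, term_vocab),
             match(tab$doc_token, doc_vocab))] <- tab$probability
  structure(list(t = tmat, term_vocab = term_vocab, doc_vocab = doc_vocab,
                 ll = numeric(0)),
            class = "translation_table")
}
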