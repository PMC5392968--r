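# Similarity index over preprocessed documents: tf-idf cosine retrieval
# with a dynamically chosen neighbour count k.

#' k-nearest-neighbour retrieval configuration
#'
#' The neighbour count k is chosen per query between `k_min` and `k_max`:
#' the `probe` most similar documents are fetched, their mean similarity
#' s-bar is computed, and k is the clamped linear interpolation
#' `k = round(k_min + (k_max - k_min) * clamp((s_bar - sim_low) /
#' (sim_high - sim_low), 0, 1))` — the smaller the average similarity of
#' the neighbourhood, the fewer neighbours are used.
#'
#' @param k_min,k_max bounds on k (defaults 10 and 40).
#' @param probe number of candidates fetched before choosing k
#'   (default `k_max`).
#' @param sim_low,sim_high similarity thresholds anchoring the linear map;
#'   `NULL` means "use the values calibrated at index build time"
#'   (10th/90th percentile of neighbour-mean similarity on the indexed
#'   corpus).
#' @return a `knn_config` list.
#' @export
knn_config <- function(k_min = 10, k_max = 40, probe = k_max,
                       sim_low = NULL, sim_high = NULL) {
  stopifnot(k_min >= 1, k_min <= k_max, probe >= k_max)
  if (!is.null(sim_low) && !is.null(sim_high) && !(sim_low < sim_high))
    stop("sim_low must be < sim_high")
  structure(list(k_min = as.integer(k_min), k_max = as.integer(k_max),
                 probe = as.integer(probe),
                 sim_low = sim_low, sim_high = sim_high),
            class = "knn_config")
}

.doc_vector <- function(index, pdoc) {
  # tf-idf vector in the index token space, L2-normalized
  toks <- names(pdoc$tf)
  idx <- match(toks, index$tokens)
  keep <- !is.na(idx)
  v <- numeric(length(index$tokens))
  if (any(keep)) {
    v[idx[keep]] <- pdoc$tf[keep] * index$idf[idx[keep]]
    nrm <- sqrt(sum(v^2))
    if (nrm > 0) v <- v / nrm
  }
  v
}

#' Build a similarity index over a corpus
#'
#' Preprocesses every document (stop-word removal, stemming), weights
#' stemmed unigrams by tf-idf (`idf = ln(1 + n/df)`), L2-normalizes, and
#' stores the sparse token-by-document matrix for cosine retrieval. Gold
#' annotations never contribute tokens: only the running title and
#' abstract text is indexed, so similarity is based solely on the words
#' documents have in common. Document frequencies and the average document
#' length are retained for the downstream retrieval models.
#'
#' @param corpus list of `mesh_document` objects.
#' @param date_floor optional `Date`; only documents with
#'   `annotation_date >= date_floor` are indexed (recency filtering of the
#'   neighbour pool; documents with no date are dropped when a floor is
#'   set).
#' @param exclude_terms must remain `TRUE`: annotations are excluded from
#'   the text used for similarity.
#' @param stemmer,stopwords passed to [preprocess()].
#' @param calibrate logical; when `TRUE`, the dynamic-k thresholds
#'   `sim_low`/`sim_high` are set to the 10th/90th percentile of
#'   neighbour-mean similarity over (a sample of) the indexed documents.
#' @param calibrate_sample maximum number of documents used for threshold
#'   calibration.
#' @param seed seed for the calibration sample.
#' @return an object of class `mesh_index`.
#' @export
build_index <- function(corpus, date_floor = NULL, exclude_terms = TRUE,
                        stemmer = "porter", stopwords = default_stopwords(),
                        calibrate = TRUE, calibrate_sample = 200, seed = 1) {
  if (!isTRUE(exclude_terms))
    stop("annotations must be excluded from similarity text (exclude_terms = TRUE)")
  if (!is.null(date_floor)) {
    keep <- vapply(corpus, function(d)
      !is.na(d$annotation_date) && d$annotation_date >= date_floor, TRUE)
    corpus <- corpus[keep]
  }
  if (!length(corpus)) stop("no documents to index after date filtering")
  corpus <- .check_corpus(corpus)
  pdocs <- preprocess_corpus(corpus, stemmer = stemmer, stopwords = stopwords)

  tokens <- sort(unique(unlist(lapply(pdocs, function(p) names(p$tf)),
                               use.names = FALSE)))
  n <- length(pdocs)
  ii <- unlist(lapply(pdocs, function(p) match(names(p$tf), tokens)),
               use.names = FALSE)
  jj <- rep(seq_len(n), vapply(pdocs, function(p) length(p$tf), 0L))
  xx <- unlist(lapply(pdocs, function(p) unname(as.numeric(p$tf))),
               use.names = FALSE)
  tfmat <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                                dims = c(length(tokens), n))
  df <- Matrix::rowSums(tfmat > 0)
  idf <- log(1 + n / pmax(df, 1))
  mat <- tfmat * idf
  nrm <- sqrt(Matrix::colSums(mat^2))
  nrm[nrm == 0] <- 1
  mat <- mat %*% Matrix::Diagonal(x = 1 / nrm)

  index <- structure(list(
    doc_ids = names(pdocs),
    pdocs = pdocs,
    tokens = tokens,
    mat = mat,
    df = stats::setNames(as.integer(df), tokens),
    idf = idf,
    n_docs = n,
    avg_len = mean(vapply(pdocs, `[[`, 0L, "length")),
    annotations = lapply(corpus, `[[`, "gold_terms"),
    stemmer = stemmer,
    stopwords = stopwords,
    sim_low = 0, sim_high = 1), class = "mesh_index")

  if (calibrate && n >= 3) {
    set.seed(seed)
    sample_ids <- if (n > calibrate_sample)
      sort(sample(index$doc_ids, calibrate_sample)) else index$doc_ids
    probe <- min(40L, n - 1L)
    means <- vapply(sample_ids, function(id) {
      sims <- .all_sims(index, index$pdocs[[id]])
      sims <- sims[names(sims) != id]
      mean(sort(sims, decreasing = TRUE)[seq_len(probe)])
    }, 0)
    qs <- stats::quantile(means, c(0.1, 0.9), names = FALSE)
    if (qs[1] < qs[2]) {
      index$sim_low <- qs[1]
      index$sim_high <- qs[2]
    }
  }
  index
}

#' @export
print.mesh_index <- function(x, ...) {
  cat("mesh_index:", x$n_docs, "documents,", length(x$tokens), "tokens,",
      sprintf("avg length %.1f, sim thresholds [%.3f, %.3f]\n",
              x$avg_len, x$sim_low, x$sim_high))
  invisible(x)
}

.all_sims <- function(index, pdoc) {
  v <- .doc_vector(index, pdoc)
  stats::setNames(as.numeric(Matrix::crossprod(index$mat, v)), index$doc_ids)
}

#' Cosine similarity between two preprocessed documents
#'
#' tf-idf cosine using the index's idf weights; symmetric; 0 when the
#' documents share no indexed tokens; 1 for identical documents.
#'
#' @param index a `mesh_index`.
#' @param a,b `processed_doc` objects.
#' @return similarity in `[0, 1]`.
#' @export
similarity <- function(index, a, b) {
  sum(.doc_vector(index, a) * .doc_vector(index, b))
}

#' Retrieve k nearest neighbours with dynamic k
#'
#' Fetches the `cfg$probe` most similar indexed documents (the query's own
#' doc_id is always excluded), derives k from their mean similarity (see
#' [knn_config()]), and returns the top k in non-increasing similarity,
#' ties broken by doc_id.
#'
#' @param index a `mesh_index`.
#' @param q a `processed_doc` query.
#' @param cfg a [knn_config()].
#' @return data.frame with columns `doc_id` and `similarity`. If fewer
#'   than `k_min` candidates exist, all are returned and the attribute
#'   `"short"` is set to `TRUE`, with a warning.
#' @export
knn_retrieve <- function(index, q, cfg = knn_config()) {
  sims <- .all_sims(index, q)
  if (!is.na(q$doc_id)) sims <- sims[names(sims) != q$doc_id]
  if (!length(sims)) stop("index holds no candidate documents")
  ord <- order(-sims, names(sims))
  sims <- sims[ord]
  probe <- sims[seq_len(min(cfg$probe, length(sims)))]
  s_bar <- mean(probe)
  lo <- cfg$sim_low %||% index$sim_low
  hi <- cfg$sim_high %||% index$sim_high
  frac <- if (hi > lo) min(max((s_bar - lo) / (hi - lo), 0), 1) else 1
  k <- as.integer(round(cfg$k_min + (cfg$k_max - cfg$k_min) * frac))
  out <- data.frame(doc_id = names(sims)[seq_len(min(k, length(sims)))],
                    similarity = unname(sims[seq_len(min(k, length(sims)))]),
                    stringsAsFactors = FALSE)
  if (length(sims) < cfg$k_min) {
    warning("only ", length(sims), " candidates available (k_min = ",
            cfg$k_min, ")")
    attr(out, "short") <- TRUE
  }
  out
}
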