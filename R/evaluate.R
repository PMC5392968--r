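# Precision / recall / F1 for multi-label indexing: per-document
# (example-based) metrics, their corpus means, micro-averaged pooled
# metrics, and a per-label F1 table for error analysis.

#' Precision, recall and F1 of one prediction set
#'
#' Conventions: precision is 1 when both sets are empty and 0 when only
#' the prediction set is empty is not applicable (empty predictions with
#' non-empty gold give precision 0); recall is 1 when the gold set is
#' empty; F1 is the harmonic mean, 0 when precision + recall = 0.
#'
#' @param predicted character vector of predicted descriptor ids.
#' @param gold character vector of gold descriptor ids.
#' @return named numeric vector `c(precision, recall, f1)`.
#' @export
prf <- function(predicted, gold) {
  predicted <- unique(predicted)
  gold <- unique(gold)
  tp <- length(intersect(predicted, gold))
  p <- if (!length(predicted)) {
    if (!length(gold)) 1 else 0
  } else tp / length(predicted)
  r <- if (!length(gold)) 1 else tp / length(gold)
  f1 <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  c(precision = p, recall = r, f1 = f1)
}

#' Evaluate predictions over a corpus
#'
#' Example-based means of per-document precision/recall/F1, micro-averaged
#' metrics from pooled true/false positive counts, and a per-label F1
#' table.
#'
#' @param predictions named list doc_id -> character vector of predicted
#'   descriptor ids.
#' @param gold named list doc_id -> gold descriptor ids; its doc_id set
#'   must match `predictions`.
#' @return object of class `mesh_eval_report`: `per_doc` (data.frame),
#'   `example` (mean P/R/F1), `micro` (pooled P/R/F1), `per_label`
#'   (data.frame label/tp/fp/fn/precision/recall/f1), `counts`.
#' @export
evaluate_corpus <- function(predictions, gold) {
  missing_pred <- setdiff(names(gold), names(predictions))
  missing_gold <- setdiff(names(predictions), names(gold))
  if (length(missing_pred) || length(missing_gold))
    stop("doc_id mismatch between predictions and gold; missing from ",
         "predictions: [", paste(missing_pred, collapse = ", "),
         "]; missing from gold: [", paste(missing_gold, collapse = ", "), "]")
  ids <- names(gold)
  per_doc <- do.call(rbind, lapply(ids, function(id) {
    m <- prf(predictions[[id]], gold[[id]])
    data.frame(doc_id = id, precision = m[1], recall = m[2], f1 = m[3],
               n_pred = length(unique(predictions[[id]])),
               n_gold = length(unique(gold[[id]])),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  tp <- sum(vapply(ids, function(id)
    length(intersect(unique(predictions[[id]]), unique(gold[[id]]))), 0))
  n_pred <- sum(per_doc$n_pred)
  n_gold <- sum(per_doc$n_gold)
  micro_p <- if (n_pred == 0) as.numeric(n_gold == 0) else tp / n_pred
  micro_r <- if (n_gold == 0) 1 else tp / n_gold
  micro_f <- if (micro_p + micro_r == 0) 0 else
    2 * micro_p * micro_r / (micro_p + micro_r)
  labels <- sort(unique(c(unlist(predictions, use.names = FALSE),
                          unlist(gold, use.names = FALSE))))
  per_label <- do.call(rbind, lapply(labels, function(lb) {
    ltp <- sum(vapply(ids, function(id)
      lb %in% predictions[[id]] && lb %in% gold[[id]], TRUE))
    lfp <- sum(vapply(ids, function(id)
      lb %in% predictions[[id]] && !lb %in% gold[[id]], TRUE))
    lfn <- sum(vapply(ids, function(id)
      !lb %in% predictions[[id]] && lb %in% gold[[id]], TRUE))
    p <- if (ltp + lfp == 0) 0 else ltp / (ltp + lfp)
    r <- if (ltp + lfn == 0) 0 else ltp / (ltp + lfn)
    data.frame(label = lb, tp = ltp, fp = lfp, fn = lfn, precision = p,
               recall = r,
               f1 = if (p + r == 0) 0 else 2 * p * r / (p + r),
               stringsAsFactors = FALSE)
  }))
  structure(list(
    per_doc = per_doc,
    example = c(precision = mean(per_doc$precision),
                recall = mean(per_doc$recall), f1 = mean(per_doc$f1)),
    micro = c(precision = micro_p, recall = micro_r, f1 = micro_f),
    per_label = per_label,
    counts = c(n_docs = length(ids), tp = tp, n_pred = n_pred,
               n_gold = n_gold)),
    class = "mesh_eval_report")
}

#' @export
print.mesh_eval_report <- function(x, ...) {
  cat("mesh_eval_report over", x$counts["n_docs"], "documents\n")
  cat(sprintf("  example-based  P %.3f  R %.3f  F1 %.3f\n",
              x$example["precision"], x$example["recall"], x$example["f1"]))
  cat(sprintf("  micro-averaged P %.3f  R %.3f  F1 %.3f\n",
              x$micro["precision"], x$micro["recall"], x$micro["f1"]))
  invisible(x)
}
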