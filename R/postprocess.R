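# Post-processing of a ranked prediction list: (1) age check-tag
# injection from explicit age mentions in the abstract, (2) removal of
# parent terms out-ranked by a more specific descendant, (3) a
# log-weighted automatic score cut-off.

#' Pruning configuration
#'
#' The cut-off rule keeps positions 1..i for the smallest i >= 2 with
#' `S[i+1] < S[i] * ln(i) * lambda_cut`; if no position violates the
#' rule, everything (up to `n_cap`) is kept. `lambda_cut` trades recall
#' against precision; the reference setting is 0.3 with a hard cap of 25
#' terms. At i = 1 the rule would force `S[2] < 0` (ln 1 = 0) and discard
#' all but one term whenever scores are positive, so evaluation starts at
#' i = 2 (natural log).
#'
#' @param lambda_cut cut-off weight (default 0.3).
#' @param n_cap hard cap on list length (default 25).
#' @param min_keep minimum number of predictions kept (default 1).
#' @return a `pruning_config` list.
#' @export
pruning_config <- function(lambda_cut = 0.3, n_cap = 25, min_keep = 1) {
  stopifnot(lambda_cut > 0, min_keep >= 1, n_cap >= min_keep)
  structure(list(lambda_cut = lambda_cut, n_cap = as.integer(n_cap),
                 min_keep = as.integer(min_keep), log_base = "natural"),
            class = "pruning_config")
}

#' Default age check-tag rules
#'
#' Age ranges follow NLM check-tag conventions: Infant, Newborn 0-1
#' month; Infant 1-23 months; Child, Preschool 2-5 years; Child 6-12
#' years; Adolescent 13-18; Young Adult 19-24; Adult 19-44; Middle Aged
#' 45-64; Aged 65+; Aged, 80 and over 80+. Ranges may overlap (e.g. Young
#' Adult within Adult), matching indexing practice of co-assigning tags;
#' detection returns the union of matches. When a vocabulary is supplied,
#' rules are kept only for tags whose preferred name exists in it and the
#' matching descriptor ids are filled in.
#'
#' @param vocab optional `mesh_vocabulary` used to resolve tag names to
#'   descriptor ids.
#' @return an `age_rules` data.frame: `tag`, `min_months`, `max_months`,
#'   `descriptor_id`.
#' @export
default_age_rules <- function(vocab = NULL) {
  rules <- data.frame(
    tag = c("Infant, Newborn", "Infant", "Child, Preschool", "Child",
            "Adolescent", "Young Adult", "Adult", "Middle Aged", "Aged",
            "Aged, 80 and over"),
    min_months = c(0, 1, 24, 72, 156, 228, 228, 540, 780, 960),
    max_months = c(1, 23, 71, 155, 227, 299, 539, 779, Inf, Inf),
    stringsAsFactors = FALSE)
  rules$descriptor_id <- rules$tag
  if (!is.null(vocab)) {
    names_by_id <- vapply(vocab$descriptors, `[[`, "", "preferred_name")
    hit <- match(tolower(rules$tag), tolower(names_by_id))
    rules$descriptor_id <- names(vocab$descriptors)[hit]
    rules <- rules[!is.na(hit), , drop = FALSE]
  }
  structure(rules, class = c("age_rules", "data.frame"))
}

#' Detect age check tags from abstract text
#'
#' Scans a character window around each occurrence of "age"/"aged"/"ages"
#' for integers, reads an optional unit ("months"/"years"; years when
#' absent; range expressions contribute both endpoints since each number
#' is extracted), maps each age through the rules and returns the union
#' of matching tags.
#'
#' @param abstract abstract text.
#' @param rules an [default_age_rules()] table.
#' @param window number of characters examined either side of the
#'   keyword (default 60).
#' @return character vector of descriptor ids (possibly empty).
#' @export
detect_age_checktags <- function(abstract, rules = default_age_rules(),
                                 window = 60) {
  if (is.null(abstract) || !nzchar(abstract) || !nrow(rules))
    return(character())
  txt <- tolower(abstract)
  hits <- gregexpr("\\bage[sd]?\\b", txt)[[1]]
  if (hits[1] == -1) return(character())
  found <- character()
  for (pos in as.integer(hits)) {
    win <- substr(txt, max(1, pos - window), min(nchar(txt), pos + window))
    m <- gregexpr("(\\d+)(\\.\\d+)?\\s*(year|yr|month|mo\\b)?", win, perl = TRUE)
    starts <- m[[1]]
    if (starts[1] == -1) next
    frags <- regmatches(win, m)[[1]]
    for (fr in frags) {
      num <- suppressWarnings(as.numeric(sub("^(\\d+(\\.\\d+)?).*", "\\1", fr)))
      if (is.na(num)) next
      months <- if (grepl("month|mo", fr)) num else num * 12
      match_tags <- rules$descriptor_id[rules$min_months <= months &
                                          months <= rules$max_months]
      found <- union(found, match_tags)
    }
  }
  found
}

#' Remove parent terms out-ranked by a more specific term
#'
#' Indexing prefers the most specific applicable heading: when a
#' descendant of a term is ranked strictly higher than the term itself,
#' the (more general) term is removed. The relative order of the
#' survivors is unchanged; a parent ranked above all of its descendants
#' is kept.
#'
#' @param pred a `prediction_list`.
#' @param vocab a `mesh_vocabulary` containing every predicted
#'   descriptor.
#' @return the pruned `prediction_list` (ranks renumbered).
#' @export
specificity_prune <- function(pred, vocab) {
  n <- nrow(pred)
  if (n < 2) return(pred)
  .check_ids(vocab, pred$descriptor_id)
  drop <- logical(n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1)) {   # j ranked strictly higher than i
      if (is_ancestor(vocab, pred$descriptor_id[i], pred$descriptor_id[j])) {
        drop[i] <- TRUE
        break
      }
    }
  }
  out <- pred[!drop, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "doc_id") <- attr(pred, "doc_id")
  class(out) <- class(pred)
  out
}

#' Automatic score cut-off
#'
#' Truncates to `n_cap`, then keeps positions 1..i for the smallest
#' i >= 2 such that `S[i+1] < S[i] * ln(i) * lambda_cut`; keeps the whole
#' (capped) list when no position violates the rule, and never fewer
#' than `min_keep` predictions.
#'
#' @param pred a `prediction_list` ordered by non-increasing score.
#' @param cfg a [pruning_config()].
#' @return the truncated `prediction_list`.
#' @export
score_cutoff <- function(pred, cfg = pruning_config()) {
  keep <- min(nrow(pred), cfg$n_cap)
  if (keep >= 2) {
    s <- pred$score
    for (i in 2:keep) {
      if (i + 1 > keep) break
      if (s[i + 1] < s[i] * log(i) * cfg$lambda_cut) {
        keep <- i
        break
      }
    }
  }
  keep <- max(min(keep, nrow(pred)), min(cfg$min_keep, nrow(pred)))
  out <- pred[seq_len(keep), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "doc_id") <- attr(pred, "doc_id")
  class(out) <- class(pred)
  out
}

#' Full post-processing pipeline
#'
#' In order: inject detected age check tags at the head of the list
#' (score = current maximum + epsilon, so pruning cannot immediately
#' drop them) when absent; remove out-ranked parent terms; apply the
#' automatic score cut-off. Idempotent on its own output.
#'
#' @param pred a `prediction_list`.
#' @param doc the `mesh_document` being indexed (its abstract is scanned
#'   for age mentions).
#' @param vocab a `mesh_vocabulary`.
#' @param prune_cfg a [pruning_config()].
#' @param age_rules an age-rule table (default resolved against
#'   `vocab`).
#' @return the post-processed `prediction_list`.
#' @export
postprocess <- function(pred, doc, vocab, prune_cfg = pruning_config(),
                        age_rules = default_age_rules(vocab)) {
  tags <- detect_age_checktags(doc$abstract, age_rules)
  tags <- setdiff(tags, pred$descriptor_id)
  if (length(tags)) {
    top <- if (nrow(pred)) max(pred$score) else 1
    add <- data.frame(rank = NA_integer_, descriptor_id = sort(tags),
                      score = top + 1e-6, stringsAsFactors = FALSE)
    pred2 <- rbind(add, as.data.frame(pred))
    pred <- .as_prediction_list(pred2$descriptor_id, pred2$score,
                                attr(pred, "doc_id"))
  }
  pred <- specificity_prune(pred, vocab)
  score_cutoff(pred, prune_cfg)
}
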