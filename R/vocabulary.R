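#' Construct a vocabulary descriptor
#'
#' A descriptor is one main heading of a hierarchical controlled vocabulary
#' (MeSH-style): an opaque identifier, a preferred name, entry-term synonyms,
#' and one or more dot-delimited tree positions. Check tags (near-universal
#' headings such as the age groups) are flagged so post-processing can treat
#' them specially.
#'
#' The preferred name is kept disjoint from the synonym set; name lookup
#' unions the two.
#'
#' @param descriptor_id unique identifier string.
#' @param preferred_name preferred heading string.
#' @param synonyms character vector of entry terms.
#' @param tree_numbers character vector of dot-delimited tree positions.
#' @param is_check_tag logical flag.
#' @return an object of class `mesh_descriptor`.
#' @export
new_descriptor <- function(descriptor_id, preferred_name,
                           synonyms = character(),
                           tree_numbers = character(),
                           is_check_tag = FALSE) {
  stopifnot(is.character(descriptor_id), length(descriptor_id) == 1L,
            nzchar(descriptor_id),
            is.character(preferred_name), length(preferred_name) == 1L)
  if (length(tree_numbers) && any(!nzchar(tree_numbers)))
    stop("empty tree number for descriptor ", descriptor_id)
  synonyms <- setdiff(unique(as.character(synonyms)), preferred_name)
  structure(list(descriptor_id = descriptor_id,
                 preferred_name = preferred_name,
                 synonyms = synonyms,
                 tree_numbers = unique(as.character(tree_numbers)),
                 is_check_tag = isTRUE(is_check_tag)),
            class = "mesh_descriptor")
}

#' Construct a vocabulary from descriptors
#'
#' @param descriptors list of [new_descriptor()] objects.
#' @return an object of class `mesh_vocabulary` with fields `descriptors`
#'   (named list keyed by id), `tree_to_id` (tree number to id map) and
#'   `label_freq` (named numeric, annotation counts; zero until
#'   [set_label_frequencies()] is called).
#' @export
new_vocabulary <- function(descriptors) {
  ids <- vapply(descriptors, `[[`, "", "descriptor_id")
  if (anyDuplicated(ids))
    stop("duplicate descriptor_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(descriptors) <- ids
  trees <- lapply(descriptors, `[[`, "tree_numbers")
  tree_to_id <- rep(ids, lengths(trees))
  names(tree_to_id) <- unlist(trees, use.names = FALSE)
  if (anyDuplicated(names(tree_to_id)))
    stop("tree number claimed by more than one descriptor: ",
         paste(unique(names(tree_to_id)[duplicated(names(tree_to_id))]),
               collapse = ", "))
  label_freq <- stats::setNames(numeric(length(ids)), ids)
  structure(list(descriptors = descriptors,
                 tree_to_id = tree_to_id,
                 label_freq = label_freq),
            class = "mesh_vocabulary")
}

#' @export
print.mesh_vocabulary <- function(x, ...) {
  cat("mesh_vocabulary:", length(x$descriptors), "descriptors,",
      sum(vapply(x$descriptors, `[[`, TRUE, "is_check_tag")), "check tags,",
      length(x$tree_to_id), "tree positions\n")
  invisible(x)
}

#' @export
length.mesh_vocabulary <- function(x) length(x$descriptors)

.check_ids <- function(v, ids) {
  missing <- setdiff(ids, names(v$descriptors))
  if (length(missing))
    stop("unknown descriptor id(s): ", paste(missing, collapse = ", "))
}

parent_tree <- function(tree_number) {
  has_dot <- grepl(".", tree_number, fixed = TRUE)
  out <- rep(NA_character_, length(tree_number))
  out[has_dot] <- sub("\\.[^.]+$", "", tree_number[has_dot])
  out
}

#' Ancestors of a descriptor
#'
#' All descriptors whose tree numbers are strict dot-prefixes of any of the
#' given descriptor's tree numbers, found by walking the parent map upward.
#'
#' @param v a `mesh_vocabulary`.
#' @param descriptor_id a descriptor id present in `v`.
#' @return character vector of ancestor descriptor ids (possibly empty).
#' @export
ancestors <- function(v, descriptor_id) {
  .check_ids(v, descriptor_id)
  out <- character()
  frontier <- v$descriptors[[descriptor_id]]$tree_numbers
  while (length(frontier)) {
    frontier <- unique(parent_tree(frontier))
    frontier <- frontier[!is.na(frontier)]
    out <- c(out, unname(v$tree_to_id[frontier[frontier %in% names(v$tree_to_id)]]))
  }
  setdiff(unique(out), descriptor_id)
}

#' Descendants of a descriptor
#'
#' @inheritParams ancestors
#' @return character vector of descendant descriptor ids.
#' @export
descendants <- function(v, descriptor_id) {
  .check_ids(v, descriptor_id)
  own <- v$descriptors[[descriptor_id]]$tree_numbers
  all_trees <- names(v$tree_to_id)
  hit <- rep(FALSE, length(all_trees))
  for (tn in own)
    hit <- hit | startsWith(all_trees, paste0(tn, "."))
  setdiff(unique(unname(v$tree_to_id[hit])), descriptor_id)
}

#' Is one descriptor an ancestor of another?
#'
#' True iff some tree number of `a` is a strict dot-prefix of some tree
#' number of `b`. Strict: a descriptor is never its own ancestor.
#'
#' @param v a `mesh_vocabulary`.
#' @param a,b descriptor ids.
#' @return logical scalar.
#' @export
is_ancestor <- function(v, a, b) {
  .check_ids(v, c(a, b))
  ta <- v$descriptors[[a]]$tree_numbers
  tb <- v$descriptors[[b]]$tree_numbers
  for (x in ta)
    if (any(startsWith(tb, paste0(x, "."))))
      return(TRUE)
  FALSE
}

#' Most frequently annotated labels
#'
#' Ranks descriptors by training-annotation count (see
#' [set_label_frequencies()]), non-increasing, ties broken lexicographically
#' by id. Used to choose which labels get a binary classifier; the reference
#' configuration takes the 20,000 most frequent headings.
#'
#' @param v a `mesh_vocabulary` with populated `label_freq`.
#' @param n number of ids to return; if larger than the vocabulary, all ids
#'   are returned.
#' @return character vector of descriptor ids.
#' @export
top_frequent_labels <- function(v, n) {
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("n must be a positive count")
  ids <- names(v$label_freq)
  ord <- order(-v$label_freq, ids)
  ids[ord][seq_len(min(n, length(ids)))]
}

#' Populate label frequencies from a training corpus
#'
#' Counts one occurrence per (document, descriptor) pair. Documents can be
#' restricted by annotation date, mirroring recency-filtered training
#' (e.g. only articles indexed after a given year).
#'
#' @param v a `mesh_vocabulary`.
#' @param corpus a list of documents (see [new_document()]).
#' @param date_floor optional `Date`; documents annotated before it are
#'   ignored.
#' @return the vocabulary with `label_freq` updated.
#' @export
set_label_frequencies <- function(v, corpus, date_floor = NULL) {
  v$label_freq[] <- 0
  for (d in corpus) {
    if (!is.null(date_floor) &&
        (is.null(d$annotation_date) || is.na(d$annotation_date) ||
         d$annotation_date < date_floor))
      next
    terms <- unique(d$gold_terms)
    terms <- terms[terms %in% names(v$label_freq)]
    v$label_freq[terms] <- v$label_freq[terms] + 1
  }
  v
}

#' Load a vocabulary from disk
#'
#' Two dialects are supported: `"tsv"`, this package's plain-text exchange
#' format (header `descriptor_id name synonyms tree_numbers is_check_tag`,
#' pipe-separated multi-valued fields), and `"mesh-xml"`, the NLM descriptor
#' XML schema (`DescriptorRecord` elements; `DescriptorUI`,
#' `DescriptorName/String`, `TermList/Term/String`, `TreeNumberList`).
#'
#' @param path file path.
#' @param dialect `"tsv"` or `"mesh-xml"`.
#' @param check_tags character vector of descriptor ids or preferred names
#'   to flag as check tags (applied on top of any flags in the file).
#' @return a `mesh_vocabulary`.
#' @export
load_vocabulary <- function(path, dialect = c("tsv", "mesh-xml"),
                            check_tags = character()) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("vocabulary file not found: ", path)
  desc <- switch(dialect,
                 "tsv" = .load_vocab_tsv(path),
                 "mesh-xml" = .load_vocab_xml(path))
  if (!length(desc)) stop("no descriptors found in ", path)
  if (length(check_tags)) {
    desc <- lapply(desc, function(d) {
      if (d$descriptor_id %in% check_tags || d$preferred_name %in% check_tags)
        d$is_check_tag <- TRUE
      d
    })
  }
  new_vocabulary(desc)
}

.split_pipe <- function(x) {
  if (is.na(x) || !nzchar(x)) character() else strsplit(x, "|", fixed = TRUE)[[1]]
}

.load_vocab_tsv <- function(path) {
  tab <- tryCatch(
    utils::read.delim(path, colClasses = "character", quote = "",
                      stringsAsFactors = FALSE),
    error = function(e) stop("cannot parse vocabulary TSV ", path, ": ",
                             conditionMessage(e)))
  need <- c("descriptor_id", "name", "synonyms", "tree_numbers", "is_check_tag")
  if (!all(need %in% names(tab)))
    stop("vocabulary TSV ", path, " lacks column(s): ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  lapply(seq_len(nrow(tab)), function(i) {
    new_descriptor(tab$descriptor_id[i], tab$name[i],
                   synonyms = .split_pipe(tab$synonyms[i]),
                   tree_numbers = .split_pipe(tab$tree_numbers[i]),
                   is_check_tag = tab$is_check_tag[i] %in% c("1", "TRUE", "true"))
  })
}

.load_vocab_xml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("cannot parse descriptor XML ",
                                           path, ": ", conditionMessage(e)))
  recs <- xml2::xml_find_all(doc, ".//DescriptorRecord")
  lapply(recs, function(r) {
    id <- xml2::xml_text(xml2::xml_find_first(r, "./DescriptorUI"))
    nm <- xml2::xml_text(xml2::xml_find_first(r, "./DescriptorName/String"))
    if (!nzchar(id) || is.na(id))
      stop("DescriptorRecord without DescriptorUI in ", path)
    syn <- xml2::xml_text(xml2::xml_find_all(
      r, ".//ConceptList//TermList/Term/String"))
    trees <- xml2::xml_text(xml2::xml_find_all(
      r, "./TreeNumberList/TreeNumber"))
    new_descriptor(id, nm, synonyms = setdiff(syn, nm), tree_numbers = trees)
  })
}

#' Write a vocabulary in the TSV dialect
#'
#' @param v a `mesh_vocabulary`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vocabulary_tsv <- function(v, path) {
  rows <- vapply(v$descriptors, function(d) {
    paste(d$descriptor_id, d$preferred_name,
          paste(d$synonyms, collapse = "|"),
          paste(d$tree_numbers, collapse = "|"),
          as.integer(d$is_check_tag), sep = "\t")
  }, "")
  writeLines(c("descriptor_id\tname\tsynonyms\ttree_numbers\tis_check_tag",
               unname(rows)), path)
  invisible(path)
}

#' Preferred-name and synonym strings of a descriptor
#'
#' @param v a `mesh_vocabulary`.
#' @param descriptor_id a descriptor id.
#' @return character vector: preferred name first, then synonyms.
#' @export
term_names <- function(v, descriptor_id) {
  .check_ids(v, descriptor_id)
  d <- v$descriptors[[descriptor_id]]
  c(d$preferred_name, d$synonyms)
}
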