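#' Construct a document
#'
#' A document is an identifier, a title, an abstract, an optional set of
#' gold-standard descriptor annotations (used for training and evaluation)
#' and an optional annotation date (used for recency filtering of the
#' neighbour index).
#'
#' @param doc_id unique identifier string.
#' @param title title text.
#' @param abstract abstract text.
#' @param gold_terms character vector of descriptor ids (may be empty).
#' @param annotation_date a `Date`, or `NA`.
#' @return an object of class `mesh_document`.
#' @export
new_document <- function(doc_id, title = "", abstract = "",
                         gold_terms = character(),
                         annotation_date = as.Date(NA)) {
  stopifnot(is.character(doc_id), length(doc_id) == 1L, nzchar(doc_id))
  title <- if (is.null(title) || is.na(title)) "" else as.character(title)
  abstract <- if (is.null(abstract) || is.na(abstract)) "" else as.character(abstract)
  if (!nzchar(title) && !nzchar(abstract))
    stop("document ", doc_id, ": title and abstract are both empty")
  structure(list(doc_id = doc_id, title = title, abstract = abstract,
                 gold_terms = unique(as.character(gold_terms)),
                 annotation_date = as.Date(annotation_date)),
            class = "mesh_document")
}

.check_corpus <- function(corpus) {
  ids <- vapply(corpus, `[[`, "", "doc_id")
  if (anyDuplicated(ids))
    stop("duplicate doc_id in corpus: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(corpus) <- ids
  corpus
}

#' Read a corpus from JSON Lines
#'
#' One JSON object per line with fields `doc_id`, `title`, `abstract`,
#' optional `gold_terms` (array of strings) and `annotation_date`
#' (`YYYY-MM-DD`).
#'
#' @param path file path.
#' @return named list of `mesh_document` objects, keyed by doc_id.
#' @export
read_corpus_jsonl <- function(path) {
  if (!file.exists(path)) stop("corpus file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty corpus file: ", path)
  docs <- lapply(seq_along(lines), function(i) {
    rec <- tryCatch(jsonlite::fromJSON(lines[[i]]),
                    error = function(e) stop("corpus ", path, " line ", i,
                                             ": ", conditionMessage(e)))
    new_document(rec$doc_id,
                 title = rec$title %||% "",
                 abstract = rec$abstract %||% "",
                 gold_terms = unlist(rec$gold_terms) %||% character(),
                 annotation_date =
                   if (is.null(rec$annotation_date)) as.Date(NA)
                   else as.Date(rec$annotation_date))
  })
  .check_corpus(docs)
}

#' Write a corpus as JSON Lines
#'
#' @param corpus list of `mesh_document` objects.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_corpus_jsonl <- function(corpus, path) {
  lines <- vapply(corpus, function(d) {
    rec <- list(doc_id = d$doc_id, title = d$title, abstract = d$abstract,
                gold_terms = I(d$gold_terms))
    if (!is.na(d$annotation_date))
      rec$annotation_date <- format(d$annotation_date)
    jsonlite::toJSON(rec, auto_unbox = TRUE)
  }, "")
  writeLines(unname(lines), path)
  invisible(path)
}

#' Read a corpus from MEDLINE-style XML
#'
#' Understands the citation layout of PubMed exports: `PMID`,
#' `Article/ArticleTitle`, `Abstract/AbstractText` (concatenating structured
#' abstract sections), `MeshHeadingList/MeshHeading/DescriptorName/@UI`, and
#' `DateCompleted`.
#'
#' @param path file path.
#' @return named list of `mesh_document` objects.
#' @export
read_corpus_medline_xml <- function(path) {
  if (!file.exists(path)) stop("corpus file not found: ", path)
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("cannot parse MEDLINE XML ", path,
                                           ": ", conditionMessage(e)))
  cits <- xml2::xml_find_all(doc, ".//MedlineCitation")
  if (!length(cits)) stop("no MedlineCitation records in ", path)
  docs <- lapply(cits, function(cit) {
    pmid <- xml2::xml_text(xml2::xml_find_first(cit, "./PMID"))
    title <- xml2::xml_text(xml2::xml_find_first(cit, ".//ArticleTitle"))
    abs_parts <- xml2::xml_text(xml2::xml_find_all(cit, ".//Abstract/AbstractText"))
    terms <- xml2::xml_attr(
      xml2::xml_find_all(cit, ".//MeshHeadingList/MeshHeading/DescriptorName"),
      "UI")
    dc <- xml2::xml_find_first(cit, "./DateCompleted")
    ad <- as.Date(NA)
    if (!inherits(dc, "xml_missing")) {
      y <- xml2::xml_text(xml2::xml_find_first(dc, "./Year"))
      m <- xml2::xml_text(xml2::xml_find_first(dc, "./Month"))
      d <- xml2::xml_text(xml2::xml_find_first(dc, "./Day"))
      ad <- suppressWarnings(as.Date(sprintf("%s-%02d-%02d", y,
                                             as.integer(m), as.integer(d))))
    }
    new_document(pmid, title = if (is.na(title)) "" else title,
                 abstract = paste(abs_parts, collapse = " "),
                 gold_terms = terms[!is.na(terms)],
                 annotation_date = ad)
  })
  .check_corpus(docs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
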