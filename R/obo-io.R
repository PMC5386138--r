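# OBO 1.2 flat-file reader/writer.
#
# Only the tags the index layer consumes are retained: id, name, is_a,
# relationship, alt_id, is_obsolete, replaced_by.  Everything else (def,
# xref, synonym, subset, ...) plays no role downstream and is discarded.

#' Parse an ontology in OBO 1.2 flat-file format
#'
#' Reads an OBO document into a faithful in-memory representation.  Only
#' `[Term]` stanzas are parsed; other stanza types (e.g. `[Typedef]`) are
#' skipped and counted.  Trailing comments introduced by `" ! "` are stripped
#' from tag values; unknown tags within a stanza are ignored.  Parsing is
#' insensitive to Windows line endings and trailing whitespace.
#'
#' @param x a file path, a single string, or a character vector of lines.
#' @return An object of class `obo_document`: a list with components
#'   `header` (list of `c(tag, value)` pairs), `terms` (ordered list of
#'   `obo_term` records) and `skipped_stanzas` (count of non-Term stanzas).
#' @examples
#' doc <- parse_obo(c(
#'   "format-version: 1.2", "",
#'   "[Term]", "id: T:001", "name: root", "",
#'   "[Term]", "id: T:002", "name: child", "is_a: T:001 ! root"))
#' length(doc$terms)
#' @export
parse_obo <- function(x) {
  lines <- as_lines(x)
  n <- length(lines)
  stanza_starts <- grep("^\\[", lines)

  header_end <- if (length(stanza_starts)) stanza_starts[1] - 1L else n
  header <- list()
  if (header_end >= 1L) {
    for (ln in lines[seq_len(header_end)]) {
      if (!nzchar(ln)) next
      tv <- split_tag(ln)
      if (!is.null(tv)) header[[length(header) + 1L]] <- tv
    }
  }

  terms <- list()
  seen_ids <- character()
  skipped <- 0L
  for (k in seq_along(stanza_starts)) {
    start <- stanza_starts[k]
    end <- if (k < length(stanza_starts)) stanza_starts[k + 1] - 1L else n
    head_line <- lines[start]
    if (!identical(head_line, "[Term]")) {
      skipped <- skipped + 1L
      next
    }
    term <- parse_term_stanza(lines[seq.int(start + 1L, length.out = end - start)],
                              line_no = start)
    if (term$id %in% seen_ids) {
      obk_stop(sprintf("duplicate term id '%s' (stanza at line %d)", term$id, start),
               "obokit_duplicate_id")
    }
    seen_ids <- c(seen_ids, term$id)
    terms[[length(terms) + 1L]] <- term
  }
  names(terms) <- seen_ids

  # no alt_id may collide with a primary id
  all_alts <- unlist(lapply(terms, `[[`, "alt_ids"), use.names = FALSE)
  clash <- intersect(all_alts, seen_ids)
  if (length(clash)) {
    obk_stop(paste0("alt_id collides with primary term id: ",
                    paste(clash, collapse = ", ")),
             "obokit_duplicate_id")
  }

  structure(list(header = header, terms = terms, skipped_stanzas = skipped),
            class = "obo_document")
}

# Split "tag: value" on the first colon; strip " ! " comments (first
# occurrence of space-bang-space only, so names containing "!" survive).
split_tag <- function(line) {
  i <- regexpr(":", line, fixed = TRUE)
  if (i < 1L) return(NULL)
  tag <- substr(line, 1L, i - 1L)
  value <- trimws(substr(line, i + 1L, nchar(line)))
  j <- regexpr(" ! ", value, fixed = TRUE)
  if (j > 0L) value <- trimws(substr(value, 1L, j - 1L))
  c(tag, value)
}

parse_term_stanza <- function(body, line_no) {
  id <- NA_character_
  name <- NA_character_
  is_a <- character()
  rels <- list()
  alt_ids <- character()
  obsolete <- FALSE
  replaced_by <- NA_character_
  for (ln in body) {
    if (!nzchar(ln)) next
    tv <- split_tag(ln)
    if (is.null(tv)) next
    tag <- tv[1]; value <- tv[2]
    if (tag == "id") id <- value
    else if (tag == "name") name <- value
    else if (tag == "is_a") is_a <- c(is_a, value)
    else if (tag == "relationship") {
      parts <- strsplit(value, "[ \t]+")[[1]]
      if (length(parts) >= 2L) rels[[length(rels) + 1L]] <- c(parts[1], parts[2])
    }
    else if (tag == "alt_id") alt_ids <- c(alt_ids, value)
    else if (tag == "is_obsolete") obsolete <- identical(tolower(value), "true")
    else if (tag == "replaced_by") replaced_by <- value
    # all other tags ignored
  }
  if (is.na(id) || !nzchar(id)) {
    obk_stop(sprintf("[Term] stanza starting at line %d has no id tag", line_no),
             "obokit_parse_error")
  }
  if (!is.na(replaced_by) && !obsolete) {
    warning(sprintf("term '%s' has replaced_by but is not obsolete", id),
            call. = FALSE)
  }
  obo_term(id = id, name = name, is_a_parents = unique(is_a),
           relationships = rels, alt_ids = unique(alt_ids),
           is_obsolete = obsolete, replaced_by = replaced_by)
}

#' Construct an OBO term record
#'
#' @param id term ID (non-empty string).
#' @param name term name.
#' @param is_a_parents character vector of parent term IDs ('is-a' targets).
#' @param relationships list of `c(relation_type, target_id)` pairs.
#' @param alt_ids character vector of alternate IDs for this term.
#' @param is_obsolete logical obsolescence flag.
#' @param replaced_by replacement term ID, or `NA`.
#' @return An object of class `obo_term`.
#' @export
obo_term <- function(id, name = NA_character_, is_a_parents = character(),
                     relationships = list(), alt_ids = character(),
                     is_obsolete = FALSE, replaced_by = NA_character_) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  structure(list(id = id, name = name,
                 is_a_parents = as.character(is_a_parents),
                 relationships = relationships,
                 alt_ids = as.character(alt_ids),
                 is_obsolete = isTRUE(is_obsolete),
                 replaced_by = replaced_by),
            class = "obo_term")
}

#' Construct an OBO document from term records
#'
#' @param terms list of [obo_term()] records.
#' @param header list of `c(tag, value)` header pairs.
#' @return An object of class `obo_document`.
#' @export
obo_document <- function(terms, header = list(c("format-version", "1.2"))) {
  names(terms) <- vapply(terms, `[[`, character(1), "id")
  if (anyDuplicated(names(terms))) {
    obk_stop("duplicate term ids in document", "obokit_duplicate_id")
  }
  structure(list(header = header, terms = terms, skipped_stanzas = 0L),
            class = "obo_document")
}

#' Serialize an ontology to OBO 1.2 text
#'
#' Emits the header then one `[Term]` stanza per term in document order, with
#' a fixed tag order (id, name, alt_id, is_a, relationship, is_obsolete,
#' replaced_by) so output is byte-stable.  `parse_obo(write_obo(doc))`
#' reproduces `doc` on the retained tag set.
#'
#' @param doc an `obo_document`.
#' @param path optional file path; if given the text is also written there.
#' @return The OBO text as a single string (invisibly when `path` is given).
#' @export
write_obo <- function(doc, path = NULL) {
  stopifnot(inherits(doc, "obo_document"))
  out <- vapply(doc$header, function(tv) paste0(tv[1], ": ", tv[2]), character(1))
  for (term in doc$terms) {
    stanza <- c("", "[Term]", paste0("id: ", term$id))
    if (!is.na(term$name)) stanza <- c(stanza, paste0("name: ", term$name))
    stanza <- c(stanza,
                paste0("alt_id: ", term$alt_ids, recycle0 = TRUE),
                paste0("is_a: ", term$is_a_parents, recycle0 = TRUE),
                vapply(term$relationships,
                       function(r) paste0("relationship: ", r[1], " ", r[2]),
                       character(1)))
    if (term$is_obsolete) stanza <- c(stanza, "is_obsolete: true")
    if (!is.na(term$replaced_by)) {
      stanza <- c(stanza, paste0("replaced_by: ", term$replaced_by))
    }
    out <- c(out, stanza)
  }
  text <- paste0(paste(out, collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(text, path, sep = "")
    return(invisible(text))
  }
  text
}

#' @export
print.obo_document <- function(x, ...) {
  cat(sprintf("OBO document: %d terms, %d header lines, %d skipped stanzas\n",
              length(x$terms), length(x$header), x$skipped_stanzas))
  invisible(x)
}
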