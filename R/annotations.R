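# Object -> term annotation tables, ancestor propagation (true-path rule)
# and corpus-frequency information content.

#' Read a two-column annotation table
#'
#' Expects tab-separated `object<TAB>term` rows; repeated object IDs
#' accumulate terms.  Term IDs are resolved through the index (alternate IDs
#' and replaced obsolete IDs map to their primary term); rows whose term
#' cannot be resolved are dropped with a warning summary.
#'
#' @param x file path, single string, or character vector of lines.
#' @param index an `onto_index` used to resolve term IDs.
#' @return An `annotation_set`: list with `objects` (IDs in first-appearance
#'   order), `terms_of` (named list of sorted term-ID vectors), `propagated`
#'   (`FALSE`) and `n_dropped` (count of unresolvable rows).
#' @export
read_annotations <- function(x, index) {
  lines <- as_lines(x)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  terms_of <- list()
  dropped <- 0L
  for (i in which(keep)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) != 2L || !all(nzchar(fields))) {
      obk_stop(sprintf("malformed annotation row at line %d (need 2 tab-separated columns)", i),
               "obokit_parse_error")
    }
    term <- tryCatch(resolve_term(index, fields[2]), obokit_error = function(e) NULL)
    if (is.null(term)) {
      dropped <- dropped + 1L
      next
    }
    obj <- fields[1]
    terms_of[[obj]] <- c(terms_of[[obj]], term)
  }
  if (dropped > 0L) {
    warning(sprintf("dropped %d annotation row(s) with unresolvable term IDs", dropped),
            call. = FALSE)
  }
  annotation_set(lapply(terms_of, function(v) sort(unique(v))),
                 propagated = FALSE, n_dropped = dropped)
}

#' Construct an annotation set from a named list
#'
#' @param terms_of named list mapping object IDs to character vectors of
#'   term IDs.
#' @param propagated whether the term sets are already closed under ancestors.
#' @param n_dropped bookkeeping count of dropped input rows.
#' @return An object of class `annotation_set`.
#' @export
annotation_set <- function(terms_of, propagated = FALSE, n_dropped = 0L) {
  stopifnot(is.list(terms_of))
  if (length(terms_of) && is.null(names(terms_of))) {
    stop("terms_of must be a named list (names are object IDs)")
  }
  if (anyDuplicated(names(terms_of))) stop("object IDs must be unique")
  structure(list(objects = names(terms_of),
                 terms_of = lapply(terms_of, function(v) sort(unique(as.character(v)))),
                 propagated = isTRUE(propagated),
                 n_dropped = n_dropped),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("annotation set: %d objects, %s, %d rows dropped\n",
              length(x$objects),
              if (x$propagated) "propagated" else "raw",
              x$n_dropped))
  invisible(x)
}

#' Propagate annotations through the ontology
#'
#' Replaces each object's term set by the union of the reflexive ancestors
#' of its terms (the true-path rule).  Idempotent.
#'
#' @param index an `onto_index`.
#' @param tab an `annotation_set`.
#' @return The propagated `annotation_set`.
#' @export
propagate_annotations <- function(index, tab) {
  stopifnot(inherits(tab, "annotation_set"))
  if (tab$propagated) return(tab)
  closed <- lapply(tab$terms_of, function(ts) {
    if (!length(ts)) return(character(0))
    sort(unique(unlist(index$ancestors[resolve_terms(index, ts)],
                       use.names = FALSE)))
  })
  annotation_set(closed, propagated = TRUE, n_dropped = tab$n_dropped)
}

#' Information content of terms from annotation frequency
#'
#' For each term annotated (after ancestor propagation) to `n_t` of the `N`
#' objects, the information content is `-log(n_t / N)` in nats.  Terms
#' annotated to no object are absent from the table; consumers looking them
#' up raise a no-frequency error.
#'
#' @param index an `onto_index`.
#' @param tab an `annotation_set` (propagated internally if raw).
#' @return An `ic_table`: list with `ic` (named numeric, nats), `counts`
#'   (named integer) and `n_objects`.
#' @examples
#' # a term annotated to every object has information content 0
#' @export
information_content <- function(index, tab) {
  stopifnot(inherits(tab, "annotation_set"))
  if (!tab$propagated) tab <- propagate_annotations(index, tab)
  n_obj <- length(tab$objects)
  if (n_obj == 0L) {
    obk_stop("annotation table has no objects: cannot estimate term frequencies",
             "obokit_empty_corpus")
  }
  tokens <- unlist(tab$terms_of, use.names = FALSE)
  counts <- table(tokens)
  counts <- stats::setNames(as.integer(counts), names(counts))
  counts <- counts[order(names(counts))]
  structure(list(ic = -log(counts / n_obj),
                 counts = counts,
                 n_objects = n_obj),
            class = "ic_table")
}

#' @export
print.ic_table <- function(x, ...) {
  cat(sprintf("information content: %d terms over %d objects (nats)\n",
              length(x$ic), x$n_objects))
  invisible(x)
}

#' Serialize an IC table to TSV
#'
#' Columns `term`, `count`, `ic` (6 decimal places), sorted by term ID.
#'
#' @param ic an `ic_table`.
#' @param path optional output path.
#' @return Character vector of TSV lines (invisibly when `path` is given).
#' @export
write_ic <- function(ic, path = NULL) {
  stopifnot(inherits(ic, "ic_table"))
  terms <- sort(names(ic$ic))
  lines <- c("term\tcount\tic",
             sprintf("%s\t%d\t%.6f", terms, ic$counts[terms], ic$ic[terms]))
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
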