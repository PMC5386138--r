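# Seeded generators for random single-rooted ontologies and annotation
# corpora, so every operation in the package is testable offline with
# inputs indistinguishable from real OBO / TSV files.

#' Generate a random single-rooted ontology
#'
#' Terms `T:0000001 .. T:<n>` are created in topological order: term 1 is
#' the unique root, and each later term `i` draws
#' `min(1 + Poisson(mean_parents - 1), i - 1)` parents uniformly from the
#' earlier terms, so the result is acyclic and single-rooted by
#' construction.  Deterministic given `seed`.
#'
#' @param n_terms number of terms (>= 1).
#' @param mean_parents mean number of parents per non-root term (>= 1).
#' @param seed RNG seed.
#' @return An `obo_document` that serializes to standard OBO.
#' @export
random_dag <- function(n_terms, mean_parents = 2, seed = 1L) {
  stopifnot(n_terms >= 1L, mean_parents >= 1)
  ids <- sprintf("T:%07d", seq_len(n_terms))
  with_rng_seed(seed, {
    terms <- vector("list", n_terms)
    for (i in seq_len(n_terms)) {
      parents <- character(0)
      if (i > 1L) {
        k <- min(1L + stats::rpois(1L, mean_parents - 1), i - 1L)
        parents <- ids[sort(sample.int(i - 1L, k))]
      }
      terms[[i]] <- obo_term(id = ids[i],
                             name = sprintf("synthetic term %d", i),
                             is_a_parents = parents)
    }
    obo_document(terms, header = list(c("format-version", "1.2"),
                                      c("ontology", "synthetic")))
  })
}

#' Generate a random annotation corpus over an ontology
#'
#' Each object draws `terms_per_object` terms uniformly (with replacement,
#' then deduplicated) from the non-obsolete terms of the index — the
#' simplest exchangeable null.  If `planted_group` is given, the first
#' `planted_group` objects additionally share one uniformly chosen leaf
#' term, planting a similarity signal for power studies of the group
#' permutation test.  Deterministic given `seed`.
#'
#' @param index an `onto_index`.
#' @param n_objects number of annotated objects.
#' @param terms_per_object raw terms drawn per object (>= 1).
#' @param planted_group optional integer: size of the planted cluster.
#' @param seed RNG seed.
#' @return A raw (unpropagated) `annotation_set`; when a group is planted,
#'   the shared term is recorded in the `"planted_term"` attribute.
#' @export
random_annotations <- function(index, n_objects, terms_per_object,
                               planted_group = NULL, seed = 1L) {
  stopifnot(n_objects >= 1L, terms_per_object >= 1L)
  objs <- sprintf("obj%04d", seq_len(n_objects))
  with_rng_seed(seed, {
    terms_of <- lapply(objs, function(o) {
      unique(sample(index$terms, terms_per_object, replace = TRUE))
    })
    names(terms_of) <- objs
    planted_term <- NULL
    if (!is.null(planted_group)) {
      g <- as.integer(planted_group)
      stopifnot(g >= 1L, g <= n_objects)
      leaves <- index$terms[vapply(index$children, length, integer(1)) == 0L]
      planted_term <- sample(leaves, 1L)
      for (i in seq_len(g)) {
        terms_of[[i]] <- unique(c(terms_of[[i]], planted_term))
      }
    }
    out <- annotation_set(terms_of, propagated = FALSE)
    attr(out, "planted_term") <- planted_term
    out
  })
}

#' Write an annotation set as a two-column TSV
#'
#' Inverse of [read_annotations()]: one `object<TAB>term` row per
#' annotation, objects in table order, terms sorted within object.
#'
#' @param tab an `annotation_set`.
#' @param path optional output path.
#' @return Character vector of TSV lines.
#' @export
write_annotations <- function(tab, path = NULL) {
  stopifnot(inherits(tab, "annotation_set"))
  lines <- unlist(lapply(tab$objects, function(o) {
    ts <- tab$terms_of[[o]]
    if (length(ts)) paste(o, ts, sep = "\t") else character(0)
  }), use.names = FALSE)
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
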