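# The indexed ontology: an immutable DAG with precomputed reflexive
# ancestor/descendant closures, alt-ID resolution and obsolete bookkeeping.
# Closures are materialized at build time so repeated queries are O(1)
# lookups; that trade (memory for speed) is the point of the index.

#' Build an indexed ontology from a parsed OBO document
#'
#' Parent edges are the 'is-a' edges plus the edges of any relation types
#' named in `propagate_relations` (e.g. `"part_of"`).  Obsolete terms carry
#' no edges: they appear only in the obsolete set and the alt-ID /
#' replaced-by bookkeeping.  Reflexive transitive closures (each term is its
#' own ancestor and descendant) are precomputed for every term.
#'
#' @param doc an `obo_document` from [parse_obo()].
#' @param propagate_relations character vector of relationship types to treat
#'   as parent edges in addition to `is_a` (default: none).
#' @return An object of class `onto_index` with components `terms` (active
#'   term IDs in document order), `names`, `parents`, `children`,
#'   `ancestors`, `descendants`, `alt_id_map`, `obsolete`, `replaced_by`
#'   and `roots`.
#' @examples
#' doc <- parse_obo(c("[Term]", "id: A", "", "[Term]", "id: B", "is_a: A"))
#' idx <- build_index(doc)
#' idx$ancestors[["B"]]
#' @export
build_index <- function(doc, propagate_relations = character()) {
  stopifnot(inherits(doc, "obo_document"))
  all_ids <- names(doc$terms)
  obsolete_flag <- vapply(doc$terms, `[[`, logical(1), "is_obsolete")
  active <- all_ids[!obsolete_flag]
  term_names <- vapply(doc$terms, function(t) {
    if (is.na(t$name)) t$id else t$name
  }, character(1))

  parents <- vector("list", length(active))
  names(parents) <- active
  dangling <- character()
  for (id in active) {
    term <- doc$terms[[id]]
    targets <- term$is_a_parents
    if (length(propagate_relations) && length(term$relationships)) {
      extra <- vapply(term$relationships, function(r) {
        if (r[1] %in% propagate_relations) r[2] else NA_character_
      }, character(1))
      targets <- c(targets, extra[!is.na(extra)])
    }
    undefined <- setdiff(targets, all_ids)
    dangling <- c(dangling, undefined)
    # edges into obsolete terms are dropped: obsolete terms carry no edges
    parents[[id]] <- unique(intersect(targets, active))
  }
  if (length(dangling)) {
    obk_stop(paste0("parent references to undefined terms: ",
                    paste(sort(unique(dangling)), collapse = ", ")),
             "obokit_dangling_ref")
  }

  children <- lapply(stats::setNames(vector("list", length(active)), active),
                     function(x) character(0))
  for (id in active) {
    for (p in parents[[id]]) children[[p]] <- c(children[[p]], id)
  }

  topo <- topological_order(active, parents)

  ancestors <- vector("list", length(active))
  names(ancestors) <- active
  for (id in topo) {  # parents precede children in topo order
    anc <- id
    for (p in parents[[id]]) anc <- c(anc, ancestors[[p]])
    ancestors[[id]] <- sort(unique(anc))
  }
  descendants <- vector("list", length(active))
  names(descendants) <- active
  for (id in rev(topo)) {
    dsc <- id
    for (ch in children[[id]]) dsc <- c(dsc, descendants[[ch]])
    descendants[[id]] <- sort(unique(dsc))
  }

  alt_pairs <- lapply(doc$terms, function(t) {
    stats::setNames(rep(t$id, length(t$alt_ids)), t$alt_ids)
  })
  alt_id_map <- unlist(unname(alt_pairs))
  if (is.null(alt_id_map)) alt_id_map <- character()

  replaced_by <- vapply(doc$terms, `[[`, character(1), "replaced_by")
  replaced_by <- replaced_by[!is.na(replaced_by) & obsolete_flag]

  structure(list(
    terms = active,
    names = term_names,
    parents = parents,
    children = children,
    ancestors = ancestors,
    descendants = descendants,
    alt_id_map = alt_id_map,
    obsolete = all_ids[obsolete_flag],
    replaced_by = replaced_by,
    roots = active[vapply(parents, length, integer(1)) == 0L]
  ), class = "onto_index")
}

# Kahn's algorithm; reports one concrete cycle on failure.
topological_order <- function(ids, parents) {
  indeg <- vapply(parents, length, integer(1))
  children <- lapply(stats::setNames(vector("list", length(ids)), ids),
                     function(x) character(0))
  for (id in ids) for (p in parents[[id]]) children[[p]] <- c(children[[p]], id)
  queue <- ids[indeg == 0L]
  order <- character(0)
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    order <- c(order, v)
    for (ch in children[[v]]) {
      indeg[[ch]] <- indeg[[ch]] - 1L
      if (indeg[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(order) < length(ids)) {
    cyc <- find_cycle(setdiff(ids, order), parents)
    obk_stop(paste0("cycle among parent edges: ", paste(cyc, collapse = " -> ")),
             "obokit_cycle")
  }
  order
}

# Walk parent pointers inside the residual (cyclic) subgraph until a repeat.
find_cycle <- function(residual, parents) {
  v <- residual[1]
  path <- character(0)
  while (!(v %in% path)) {
    path <- c(path, v)
    v <- intersect(parents[[v]], residual)[1]
  }
  c(path[which(path == v):length(path)], v)
}

#' @export
print.onto_index <- function(x, ...) {
  cat(sprintf("ontology index: %d terms, %d roots, %d obsolete, %d alt ids\n",
              length(x$terms), length(x$roots), length(x$obsolete),
              length(x$alt_id_map)))
  invisible(x)
}

#' Resolve a term ID against an ontology index
#'
#' Follows alternate-ID mappings and, for obsolete terms, the `replaced_by`
#' pointer.  An obsolete term without a replacement is an error rather than
#' being used silently, since stale IDs corrupt downstream statistics.
#'
#' @param index an `onto_index`.
#' @param term a single term ID (primary, alternate, or obsolete-replaced).
#' @return The primary ID of the resolved, non-obsolete term.
#' @export
resolve_term <- function(index, term) {
  seen <- character(0)
  repeat {
    if (term %in% seen) {
      obk_stop(paste0("circular alt_id/replaced_by chain at '", term, "'"),
               "obokit_unknown_term", term = term)
    }
    seen <- c(seen, term)
    if (term %in% names(index$alt_id_map)) {
      term <- index$alt_id_map[[term]]
    } else if (term %in% index$obsolete) {
      if (term %in% names(index$replaced_by)) {
        term <- index$replaced_by[[term]]
      } else {
        obk_stop(paste0("term '", term, "' is obsolete and has no replacement"),
                 "obokit_obsolete_term", term = term)
      }
    } else if (term %in% index$terms) {
      return(term)
    } else {
      obk_stop(paste0("unknown term '", term, "'"),
               "obokit_unknown_term", term = term)
    }
  }
}

resolve_terms <- function(index, terms) {
  unique(vapply(as.character(terms), resolve_term, character(1), index = index,
                USE.NAMES = FALSE))
}

#' Reflexive ancestor set of a term
#'
#' @param index an `onto_index`.
#' @param term a term ID (alt IDs and replaced obsolete IDs resolve).
#' @return Sorted character vector of ancestor IDs, including the term itself.
#' @export
ancestors <- function(index, term) {
  index$ancestors[[resolve_term(index, term)]]
}

#' Reflexive descendant set of a term
#'
#' @inheritParams ancestors
#' @return Sorted character vector of descendant IDs, including the term itself.
#' @export
descendants <- function(index, term) {
  index$descendants[[resolve_term(index, term)]]
}

#' Reduce a term set to its minimal (non-redundant) antichain
#'
#' Drops every term that is a strict ancestor of another member, leaving the
#' most specific terms only.
#'
#' @param index an `onto_index`.
#' @param terms character vector of term IDs.
#' @return Sorted character vector: the minimal subset of `terms`.
#' @export
minimal_set <- function(index, terms) {
  ts <- resolve_terms(index, terms)
  keep <- vapply(ts, function(t) {
    !any(setdiff(index$descendants[[t]], t) %in% ts)
  }, logical(1))
  sort(ts[keep])
}

#' Exclude a term set and all its descendants from another set
#'
#' Returns the members of `A` that do not descend from (or belong to) any
#' term in `B`.
#'
#' @param index an `onto_index`.
#' @param A,B character vectors of term IDs.
#' @return Sorted character vector: `A` minus the descendant closure of `B`.
#' @export
exclude_descendants <- function(index, A, B) {
  a <- resolve_terms(index, A)
  b <- resolve_terms(index, B)
  excluded <- unique(unlist(index$descendants[b], use.names = FALSE))
  sort(setdiff(a, excluded))
}

#' Exclude descendants of a set but keep its ancestral members
#'
#' Like [exclude_descendants()], but terms of `B` that are ancestors of some
#' term in `A` are retained in the result, so pruning below `B` does not
#' disconnect `A` from its ancestry.
#'
#' @inheritParams exclude_descendants
#' @return Sorted character vector.
#' @export
prune_descendants <- function(index, A, B) {
  a <- resolve_terms(index, A)
  b <- resolve_terms(index, B)
  kept <- exclude_descendants(index, a, b)
  anc_of_a <- unique(unlist(index$ancestors[a], use.names = FALSE))
  sort(union(kept, intersect(b, anc_of_a)))
}

#' Read a term list from plain text
#'
#' One term ID per line; blank lines and `#` comments are skipped.
#'
#' @param x file path or character vector of lines.
#' @return Character vector of term IDs.
#' @export
read_term_list <- function(x) {
  lines <- trimws(as_lines(x))
  lines[nzchar(lines) & !startsWith(lines, "#")]
}
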