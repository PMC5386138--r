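# Styled subgraphs of term sets for rendering with graphviz.  Edges are the
# transitive reduction of the within-set ancestor relation (not the raw
# parent edges), so scattered term sets stay connected through their nearest
# in-set ancestors.  Layout and rendering are delegated to DOT consumers.

# fill colors assigned deterministically to membership patterns; the
# pattern covering all objects gets light blue
pattern_palette <- c("palegreen", "plum", "lightgoldenrod1", "lightsalmon",
                     "paleturquoise", "thistle", "khaki", "rosybrown1",
                     "lightsteelblue1", "darkseagreen1", "mistyrose", "wheat")

#' Drop terms that add no annotation information
#'
#' A term is uninformative for display when one of its children (in the full
#' ontology) is annotated to exactly the same objects: the child says
#' everything the parent does, more specifically.  Removing such terms gives
#' markedly simpler diagrams.  Leaf terms are never removed.
#'
#' @param index an `onto_index`.
#' @param annotations a *propagated* `annotation_set`.
#' @param terms character vector of term IDs to filter; defaults to every
#'   term used in the annotations.
#' @return Sorted character vector: the informative subset of `terms`.
#' @export
remove_uninformative_terms <- function(index, annotations, terms = NULL) {
  stopifnot(inherits(annotations, "annotation_set"))
  if (!annotations$propagated) {
    obk_stop("annotations must be propagated before filtering uninformative terms",
             "obokit_not_propagated")
  }
  if (is.null(terms)) {
    terms <- unique(unlist(annotations$terms_of, use.names = FALSE))
  }
  ts <- resolve_terms(index, terms)
  objects_of <- term_object_patterns(annotations)
  pat <- function(t) {
    p <- objects_of[[t]]
    if (is.null(p)) "" else p
  }
  keep <- vapply(ts, function(t) {
    kids <- index$children[[t]]
    if (!length(kids)) return(TRUE)
    !any(vapply(kids, pat, character(1)) == pat(t))
  }, logical(1))
  sort(ts[keep])
}

# term -> collapsed sorted-object-ID pattern key
term_object_patterns <- function(annotations) {
  pairs <- lapply(annotations$objects, function(o) {
    ts <- annotations$terms_of[[o]]
    if (length(ts)) cbind(ts, o) else NULL
  })
  pairs <- do.call(rbind, pairs)
  if (is.null(pairs)) return(list())
  split_obj <- split(pairs[, 2], pairs[, 1])
  lapply(split_obj, function(os) paste(sort(unique(os)), collapse = "\x1f"))
}

#' Build a styled graph of a term set
#'
#' Nodes are the supplied terms; edges connect each term to its nearest
#' ancestors *within the set* (the transitive reduction of the induced
#' ancestor relation), drawn child to parent.  When an IC table is given,
#' node width grows affinely with information content
#' (`0.3 + 0.25 * ic`, capped at 2.5 inches); otherwise all nodes share one
#' size.  When annotation membership is given, fill colors encode which
#' objects a term is annotated to, with terms shared by all objects shown in
#' light blue.
#'
#' @param index an `onto_index`.
#' @param terms non-empty character vector of term IDs.
#' @param ic optional `ic_table` controlling node sizes.
#' @param membership optional propagated `annotation_set` (or named list of
#'   propagated term vectors) controlling fill colors.
#' @return An `onto_graph`: list with `nodes` (data frame: id, label, size,
#'   fill) and `edges` (data frame: child, parent).
#' @export
build_graph <- function(index, terms, ic = NULL, membership = NULL) {
  if (!length(terms)) obk_stop("no terms to plot", "obokit_empty_set")
  ts <- sort(resolve_terms(index, terms))

  edges <- reduce_relation(index, ts)

  labels <- vapply(ts, function(t) {
    paste(strwrap(index$names[[t]], width = 20), collapse = "\n")
  }, character(1))

  sizes <- if (is.null(ic)) {
    rep(0.75, length(ts))
  } else {
    vapply(ts, function(t) {
      v <- ic$ic[t]
      if (is.na(v)) 0.3 else min(0.3 + 0.25 * unname(v), 2.5)
    }, numeric(1))
  }

  fills <- rep("lightyellow", length(ts))
  if (!is.null(membership)) {
    if (inherits(membership, "annotation_set")) membership <- membership$terms_of
    all_objs <- sort(names(membership))
    patterns <- vapply(ts, function(t) {
      objs <- all_objs[vapply(all_objs, function(o) t %in% membership[[o]], logical(1))]
      paste(objs, collapse = "\x1f")
    }, character(1))
    shared_key <- paste(all_objs, collapse = "\x1f")
    other_keys <- sort(setdiff(unique(patterns), c("", shared_key)))
    key_color <- stats::setNames(
      rep_len(pattern_palette, length(other_keys)), other_keys)
    fills <- ifelse(patterns == shared_key, "lightblue",
                    ifelse(patterns == "", "white", key_color[patterns]))
  }

  structure(list(
    nodes = data.frame(id = ts, label = unname(labels), size = unname(sizes),
                       fill = unname(fills), stringsAsFactors = FALSE),
    edges = edges
  ), class = "onto_graph")
}

# transitive reduction of the strict-ancestor relation restricted to `ts`:
# keep (t, u) iff no third set member lies strictly between them
reduce_relation <- function(index, ts) {
  strict_anc <- lapply(stats::setNames(ts, ts), function(t) {
    intersect(setdiff(index$ancestors[[t]], t), ts)
  })
  child <- character(0)
  parent <- character(0)
  for (t in ts) {
    for (u in strict_anc[[t]]) {
      implied <- any(vapply(setdiff(strict_anc[[t]], u),
                            function(v) u %in% strict_anc[[v]], logical(1)))
      if (!implied) {
        child <- c(child, t)
        parent <- c(parent, u)
      }
    }
  }
  data.frame(child = child, parent = parent, stringsAsFactors = FALSE)
}

#' @export
print.onto_graph <- function(x, ...) {
  cat(sprintf("ontology graph: %d nodes, %d edges\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

dot_id <- function(ids) {
  sane <- gsub("[^A-Za-z0-9]", "_", ids)
  make.unique(sane, sep = "_")
}

dot_quote <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  gsub("\n", "\\n", x, fixed = TRUE)
}

#' Serialize an ontology graph to Graphviz DOT
#'
#' Nodes and edges are emitted in sorted order so serialization is
#' byte-stable.  Node identifiers are sanitized (non-alphanumeric characters
#' become underscores); the original term ID is preserved in a `tooltip`
#' attribute.
#'
#' @param graph an `onto_graph` from [build_graph()].
#' @param path optional output path.
#' @return The DOT text as a single string.
#' @export
to_dot <- function(graph, path = NULL) {
  stopifnot(inherits(graph, "onto_graph"))
  nodes <- graph$nodes[order(graph$nodes$id), , drop = FALSE]
  ids <- dot_id(nodes$id)
  node_lines <- sprintf(
    "  %s [label=\"%s\", width=%.3f, fillcolor=\"%s\", style=filled, fixedsize=true, tooltip=\"%s\"];",
    ids, dot_quote(nodes$label), nodes$size, nodes$fill, dot_quote(nodes$id))
  id_of <- stats::setNames(ids, nodes$id)
  edges <- graph$edges
  edge_lines <- character(0)
  if (nrow(edges)) {
    ord <- order(edges$child, edges$parent)
    edges <- edges[ord, , drop = FALSE]
    edge_lines <- sprintf("  %s -> %s;", id_of[edges$child], id_of[edges$parent])
  }
  text <- paste0(paste(c("digraph ontology {",
                         "  graph [overlap=false];",
                         "  node [shape=ellipse];",
                         node_lines, edge_lines, "}"),
                       collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(text, path, sep = "")
    return(invisible(text))
  }
  text
}

#' Serialize an ontology graph to GraphML
#'
#' Carries the same node attributes (label, width, fill color, term ID) as
#' the DOT output, for consumers that prefer GraphML.
#'
#' @inheritParams to_dot
#' @return The GraphML text as a single string.
#' @export
to_graphml <- function(graph, path = NULL) {
  stopifnot(inherits(graph, "onto_graph"))
  xml_escape <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    x <- gsub(">", "&gt;", x, fixed = TRUE)
    gsub("\"", "&quot;", x, fixed = TRUE)
  }
  nodes <- graph$nodes[order(graph$nodes$id), , drop = FALSE]
  node_xml <- sprintf(paste0(
    "    <node id=\"%s\"><data key=\"label\">%s</data>",
    "<data key=\"width\">%.3f</data><data key=\"fill\">%s</data></node>"),
    xml_escape(nodes$id), xml_escape(nodes$label), nodes$size,
    xml_escape(nodes$fill))
  edges <- graph$edges
  edge_xml <- character(0)
  if (nrow(edges)) {
    edges <- edges[order(edges$child, edges$parent), , drop = FALSE]
    edge_xml <- sprintf("    <edge source=\"%s\" target=\"%s\"/>",
                        xml_escape(edges$child), xml_escape(edges$parent))
  }
  text <- paste0(paste(c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    "<graphml xmlns=\"http://graphml.graphdrawing.org/xmlns\">",
    "  <key id=\"label\" for=\"node\" attr.name=\"label\" attr.type=\"string\"/>",
    "  <key id=\"width\" for=\"node\" attr.name=\"width\" attr.type=\"double\"/>",
    "  <key id=\"fill\" for=\"node\" attr.name=\"fill\" attr.type=\"string\"/>",
    "  <graph edgedefault=\"directed\">",
    node_xml, edge_xml,
    "  </graph>", "</graphml>"), collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(text, path, sep = "")
    return(invisible(text))
  }
  text
}
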