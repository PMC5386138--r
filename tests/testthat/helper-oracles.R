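# Shared fixtures and independent oracles.
#
# The oracles deliberately avoid the package's precomputed closures: they
# work directly off the parsed document's raw is_a lists by iterated
# frontier expansion, so closure bugs cannot hide in both routes.

diamond_lines <- function() {
  c("format-version: 1.2", "",
    "[Term]", "id: T:0", "name: root", "",
    "[Term]", "id: T:1", "name: left", "is_a: T:0 ! root", "",
    "[Term]", "id: T:2", "name: right", "is_a: T:0", "",
    "[Term]", "id: T:3", "name: mid", "is_a: T:1", "is_a: T:2", "",
    "[Term]", "id: T:4", "name: leaf", "is_a: T:3")
}

diamond_index <- function() build_index(parse_obo(diamond_lines()))

# X:{T:3}, Y:{T:4}, Z:{T:1}
diamond_annotations <- function(index) {
  read_annotations(c("X\tT:3", "Y\tT:4", "Z\tT:1"), index)
}

# raw is_a edge lists of a document, as a named list child -> parents
doc_parent_lists <- function(doc) {
  lapply(doc$terms, `[[`, "is_a_parents")
}

# reflexive reachability along `edges` (named list node -> targets) by
# repeated frontier expansion; independent of build_index's topo-order DP
bfs_reach <- function(edges, start) {
  seen <- character(0)
  frontier <- start
  while (length(frontier)) {
    seen <- union(seen, frontier)
    frontier <- setdiff(unique(unlist(edges[frontier], use.names = FALSE)), seen)
  }
  sort(seen)
}

invert_edges <- function(edges) {
  nodes <- names(edges)
  inv <- lapply(stats::setNames(nodes, nodes), function(x) character(0))
  for (ch in nodes) for (p in edges[[ch]]) inv[[p]] <- c(inv[[p]], ch)
  inv
}

# exact permutation p-value by enumerating every same-size subset
exact_sim_p <- function(m, group) {
  obs <- group_similarity(m, group)
  subsets <- utils::combn(nrow(m), length(group))
  null <- apply(subsets, 2, function(s) group_similarity(m, s))
  sum(null >= obs) / ncol(subsets)
}

# brute-force transitive reduction of the strict-ancestor relation on `ts`:
# drop every pair implied by a 2-step path through a third set member
brute_reduction <- function(index, ts) {
  anc <- lapply(stats::setNames(ts, ts), function(t) {
    intersect(setdiff(index$ancestors[[t]], t), ts)
  })
  pairs <- list()
  for (t in ts) for (u in anc[[t]]) {
    implied <- FALSE
    for (v in setdiff(ts, c(t, u))) {
      if (v %in% anc[[t]] && u %in% anc[[v]]) { implied <- TRUE; break }
    }
    if (!implied) pairs[[length(pairs) + 1L]] <- c(t, u)
  }
  key <- vapply(pairs, paste, character(1), collapse = "->")
  sort(key)
}

edge_keys <- function(edges) {
  if (!nrow(edges)) return(character(0))
  sort(paste(edges$child, edges$parent, sep = "->"))
}
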