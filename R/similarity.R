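# Semantic similarity at three levels: terms (Resnik / Lin), annotated
# objects (symmetric best-match average of their term sets), and groups of
# objects (mean pairwise set similarity), with a permutation test for group
# similarity strength.
#
# Resnik(t1, t2) is the information content of the most informative common
# ancestor (MICA); Lin(t1, t2) = 2 * Resnik(t1, t2) / (ic(t1) + ic(t2)),
# with the 0/0 case (two IC-zero terms) defined as 0, since root-vs-root
# similarity carries no information.

ic_of <- function(ic, term) {
  v <- ic$ic[term]
  if (is.na(v)) {
    obk_stop(paste0("term '", term, "' has no annotation frequency (no IC)"),
             "obokit_no_frequency", term = term)
  }
  unname(v)
}

# Per-term named vector of ancestor ICs, restricted to ancestors that have
# an IC entry.  This is the lookup structure behind fast MICA computation.
anc_ic_table <- function(index, ic, terms) {
  lapply(stats::setNames(terms, terms), function(t) {
    anc <- index$ancestors[[t]]
    v <- ic$ic[anc]
    v[!is.na(v)]
  })
}

mica_ic <- function(anc_ic_a, anc_ic_b) {
  common <- intersect(names(anc_ic_a), names(anc_ic_b))
  if (!length(common)) return(0)
  max(anc_ic_a[common])
}

#' Semantic similarity between two terms
#'
#' Resnik similarity is the information content of the most informative
#' common ancestor; Lin similarity normalizes it by the mean IC of the two
#' terms, giving a value in \[0, 1\].
#'
#' @param index an `onto_index`.
#' @param ic an `ic_table` from [information_content()].
#' @param t1,t2 term IDs; both must have IC entries.
#' @param method `"lin"` or `"resnik"`.
#' @return A single non-negative number; symmetric in its term arguments.
#' @export
term_similarity <- function(index, ic, t1, t2, method = c("lin", "resnik")) {
  method <- match.arg(method)
  t1 <- resolve_term(index, t1)
  t2 <- resolve_term(index, t2)
  ic1 <- ic_of(ic, t1)
  ic2 <- ic_of(ic, t2)
  tab <- anc_ic_table(index, ic, c(t1, t2))
  res <- mica_ic(tab[[t1]], tab[[t2]])
  if (method == "resnik") return(res)
  denom <- ic1 + ic2
  if (denom == 0) 0 else 2 * res / denom
}

# Cross-similarity matrix between two term vectors given precomputed
# ancestor-IC lookups; all higher-level routines funnel through here so
# cache modes cannot disagree on values.
cross_term_sim <- function(ts_a, ts_b, anc_ic, ic, method) {
  m <- matrix(0, length(ts_a), length(ts_b), dimnames = list(ts_a, ts_b))
  for (i in seq_along(ts_a)) {
    for (j in seq_along(ts_b)) {
      m[i, j] <- mica_ic(anc_ic[[ts_a[i]]], anc_ic[[ts_b[j]]])
    }
  }
  if (method == "lin") {
    ic_a <- vapply(ts_a, ic_of, numeric(1), ic = ic)
    ic_b <- vapply(ts_b, ic_of, numeric(1), ic = ic)
    denom <- outer(ic_a, ic_b, `+`)
    m <- ifelse(denom == 0, 0, 2 * m / denom)
  }
  m
}

# symmetric best-match average over a cross matrix
bma <- function(cross) {
  0.5 * (mean(apply(cross, 1, max)) + mean(apply(cross, 2, max)))
}

#' Semantic similarity between two term sets
#'
#' Symmetric best-match average: each term is matched to its best-scoring
#' partner in the other set, the per-set means are averaged.  With Lin
#' similarity and all-positive ICs, a set compared against itself scores 1.
#'
#' @param index an `onto_index`.
#' @param ic an `ic_table`.
#' @param A,B non-empty character vectors of term IDs, all with IC entries.
#' @param method `"lin"` or `"resnik"`.
#' @return A single non-negative number; symmetric in `A` and `B`.
#' @export
set_similarity <- function(index, ic, A, B, method = c("lin", "resnik")) {
  method <- match.arg(method)
  if (!length(A) || !length(B)) {
    obk_stop("set similarity of an empty term set is undefined",
             "obokit_empty_set")
  }
  a <- resolve_terms(index, A)
  b <- resolve_terms(index, B)
  anc_ic <- anc_ic_table(index, ic, union(a, b))
  for (t in union(a, b)) ic_of(ic, t)  # surface no-frequency errors by name
  bma(cross_term_sim(a, b, anc_ic, ic, method))
}

#' Pairwise similarity matrix over a list of term sets
#'
#' Computes `set_similarity()` for every pair of sets.  `cache_mode` selects
#' the precomputation strategy — `"none"` recomputes term similarities per
#' pair, `"term_matrix"` precomputes the full term-by-term matrix over the
#' union of used terms, `"set_matrix"` memoises set pairs, and
#' `"lookup_index"` precomputes per-term ancestor-IC lookups — trading time
#' for memory without ever changing the values.
#'
#' @param index an `onto_index`.
#' @param ic an `ic_table`.
#' @param sets named list of non-empty term-ID vectors (e.g. the `terms_of`
#'   of an `annotation_set`).
#' @param method `"lin"` or `"resnik"`.
#' @param cache_mode one of `"none"`, `"term_matrix"`, `"set_matrix"`,
#'   `"lookup_index"`.
#' @return A symmetric numeric matrix with the set names as dimnames.
#' @export
pairwise_set_matrix <- function(index, ic, sets,
                                method = c("lin", "resnik"),
                                cache_mode = c("none", "term_matrix",
                                               "set_matrix", "lookup_index")) {
  method <- match.arg(method)
  cache_mode <- match.arg(cache_mode)
  n <- length(sets)
  if (n == 0L) obk_stop("no term sets supplied", "obokit_empty_set")
  ids <- if (is.null(names(sets))) as.character(seq_len(n)) else names(sets)
  m <- matrix(NA_real_, n, n, dimnames = list(ids, ids))

  if (cache_mode == "none") {
    for (i in seq_len(n)) {
      for (j in i:n) {
        m[i, j] <- m[j, i] <- set_similarity(index, ic, sets[[i]], sets[[j]], method)
      }
    }
    return(m)
  }

  rsets <- lapply(sets, resolve_terms, index = index)
  all_terms <- sort(unique(unlist(rsets, use.names = FALSE)))
  if (!length(all_terms)) obk_stop("all term sets are empty", "obokit_empty_set")
  for (s in rsets) if (!length(s)) {
    obk_stop("set similarity of an empty term set is undefined", "obokit_empty_set")
  }
  anc_ic <- anc_ic_table(index, ic, all_terms)
  for (t in all_terms) ic_of(ic, t)

  if (cache_mode == "term_matrix") {
    tm <- cross_term_sim(all_terms, all_terms, anc_ic, ic, method)
    for (i in seq_len(n)) {
      for (j in i:n) {
        m[i, j] <- m[j, i] <- bma(tm[rsets[[i]], rsets[[j]], drop = FALSE])
      }
    }
  } else if (cache_mode == "lookup_index") {
    for (i in seq_len(n)) {
      for (j in i:n) {
        m[i, j] <- m[j, i] <-
          bma(cross_term_sim(rsets[[i]], rsets[[j]], anc_ic, ic, method))
      }
    }
  } else {  # set_matrix: memoise unordered set pairs keyed by term content
    memo <- new.env(parent = emptyenv())
    for (i in seq_len(n)) {
      for (j in i:n) {
        key <- paste(sort(c(paste(rsets[[i]], collapse = ","),
                            paste(rsets[[j]], collapse = ","))), collapse = "|")
        if (is.null(memo[[key]])) {
          memo[[key]] <- bma(cross_term_sim(rsets[[i]], rsets[[j]], anc_ic, ic, method))
        }
        m[i, j] <- m[j, i] <- memo[[key]]
      }
    }
  }
  m
}

check_group <- function(matrix, group) {
  if (is.character(group)) {
    idx <- match(group, rownames(matrix))
    if (anyNA(idx)) {
      obk_stop(paste0("unknown object ID(s) in group: ",
                      paste(group[is.na(idx)], collapse = ", ")),
               "obokit_unknown_term")
    }
    group <- idx
  }
  group <- as.integer(group)
  if (anyDuplicated(group) || any(group < 1L | group > nrow(matrix))) {
    obk_stop("group indices must be distinct and within the population",
             "obokit_degenerate_group")
  }
  if (length(group) < 2L) {
    obk_stop("a group needs at least 2 members", "obokit_degenerate_group")
  }
  group
}

# mean pairwise similarity for each row of a (draws x group_size) index matrix
group_stats <- function(matrix, draws) {
  g <- ncol(draws)
  pairs <- utils::combn(g, 2)
  acc <- numeric(nrow(draws))
  for (k in seq_len(ncol(pairs))) {
    acc <- acc + matrix[cbind(draws[, pairs[1, k]], draws[, pairs[2, k]])]
  }
  acc / ncol(pairs)
}

#' Mean pairwise similarity within a group of objects
#'
#' @param matrix a pairwise set-similarity matrix from
#'   [pairwise_set_matrix()].
#' @param group indices (or row names) of at least 2 distinct objects.
#' @return Mean of the matrix entries over unordered pairs in the group.
#' @export
group_similarity <- function(matrix, group) {
  group <- check_group(matrix, group)
  group_stats(matrix, matrix(group, nrow = 1L))[1]
}

#' Permutation test for group similarity
#'
#' Compares the observed within-group similarity against a null of
#' `n_permutations` uniformly drawn same-size subsets of the population,
#' using the add-one estimator `p = (1 + k) / (1 + n_permutations)` with
#' ties counted inclusively, so `p` is always in
#' `[1/(n_permutations + 1), 1]` and valid under Monte-Carlo sampling.
#'
#' @param matrix a pairwise set-similarity matrix.
#' @param group indices (or row names) of the group; must be a strict subset
#'   of the population.
#' @param n_permutations number of null draws (default 1000).
#' @param seed RNG seed, recorded in the result.
#' @return A `sim_p_result`: list with `statistic`, `p_value`,
#'   `n_permutations` and `seed`.
#' @export
sim_p <- function(matrix, group, n_permutations = 1000L, seed = 1L) {
  group <- check_group(matrix, group)
  n_permutations <- as.integer(n_permutations)
  stopifnot(n_permutations >= 1L)
  n <- nrow(matrix)
  g <- length(group)
  if (g >= n) {
    obk_stop("group spans the whole population: null distribution is degenerate",
             "obokit_degenerate_null")
  }
  observed <- group_stats(matrix, matrix(group, nrow = 1L))[1]
  null <- with_rng_seed(seed, {
    draws <- t(vapply(seq_len(n_permutations),
                      function(i) sample.int(n, g), integer(g)))
    group_stats(matrix, draws)
  })
  p <- (1 + sum(null >= observed)) / (1 + n_permutations)
  structure(list(statistic = observed, p_value = p,
                 n_permutations = n_permutations, seed = seed),
            class = "sim_p_result")
}

#' @export
print.sim_p_result <- function(x, ...) {
  cat(sprintf("group similarity %.6f, p = %.6g (%d permutations, seed %d)\n",
              x$statistic, x$p_value, x$n_permutations, x$seed))
  invisible(x)
}

#' Serialize a permutation-test result to a single TSV line
#'
#' @param res a `sim_p_result`.
#' @param path optional output path.
#' @return Character vector of two TSV lines (header + values).
#' @export
write_sim_p <- function(res, path = NULL) {
  stopifnot(inherits(res, "sim_p_result"))
  lines <- c("statistic\tp_value\tn_permutations\tseed",
             sprintf("%.6f\t%.6g\t%d\t%d",
                     res$statistic, res$p_value, res$n_permutations, res$seed))
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Serialize a pairwise similarity matrix to TSV
#'
#' Object IDs form the header row and first column; values are printed to 6
#' decimal places.
#'
#' @param m a matrix from [pairwise_set_matrix()].
#' @param path optional output path.
#' @return Character vector of TSV lines.
#' @export
write_matrix <- function(m, path = NULL) {
  ids <- rownames(m)
  lines <- c(paste(c("", ids), collapse = "\t"),
             vapply(seq_len(nrow(m)), function(i) {
               paste(c(ids[i], sprintf("%.6f", m[i, ])), collapse = "\t")
             }, character(1)))
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
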