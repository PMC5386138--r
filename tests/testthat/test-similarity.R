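# The 5-term diamond with objects X:{T:3}, Y:{T:4}, Z:{T:1} gives ICs
# T:0=0, T:1=0, T:2=-ln(2/3), T:3=-ln(2/3), T:4=-ln(1/3); all worked values
# below follow by hand from those.

diamond_ic_fixture <- function() {
  idx <- diamond_index()
  tab <- propagate_annotations(idx, diamond_annotations(idx))
  list(idx = idx, tab = tab, ic = information_content(idx, tab))
}

test_that("term similarity reproduces the worked diamond values", {
  f <- diamond_ic_fixture()
  ic3 <- -log(2 / 3); ic4 <- -log(1 / 3)
  expect_equal(term_similarity(f$idx, f$ic, "T:3", "T:4", "resnik"), ic3)
  expect_equal(term_similarity(f$idx, f$ic, "T:3", "T:4", "lin"),
               2 * ic3 / (ic3 + ic4))
  # only shared ancestry of T:1 and T:2 with IC is at IC 0; Lin 0/0 rule
  expect_equal(term_similarity(f$idx, f$ic, "T:1", "T:2", "resnik"), 0)
  expect_equal(term_similarity(f$idx, f$ic, "T:1", "T:2", "lin"), 0)
  # identity and symmetry
  expect_equal(term_similarity(f$idx, f$ic, "T:4", "T:4", "lin"), 1)
  expect_equal(term_similarity(f$idx, f$ic, "T:4", "T:3", "resnik"),
               term_similarity(f$idx, f$ic, "T:3", "T:4", "resnik"))
  err <- tryCatch(term_similarity(f$idx, f$ic, "T:3", "T:4", "nope"),
                  error = identity)
  expect_s3_class(err, "error")
})

test_that("terms without annotation frequency raise a named error", {
  idx <- diamond_index()
  # corpus leaving T:4 unannotated
  ic <- information_content(idx, annotation_set(list(X = "T:3")))
  err <- tryCatch(term_similarity(idx, ic, "T:3", "T:4"), error = identity)
  expect_s3_class(err, "obokit_no_frequency")
  expect_match(conditionMessage(err), "T:4")
})

test_that("set similarity is best-match-average with singleton collapse", {
  f <- diamond_ic_fixture()
  expect_equal(set_similarity(f$idx, f$ic, "T:3", "T:4", "lin"),
               term_similarity(f$idx, f$ic, "T:3", "T:4", "lin"))
  expect_equal(set_similarity(f$idx, f$ic, "T:3", "T:4", "lin"),
               2 * (-log(2 / 3)) / (-log(2 / 3) - log(1 / 3)))
  # self-similarity is 1 when every member has positive IC
  expect_equal(set_similarity(f$idx, f$ic, c("T:2", "T:4"), c("T:2", "T:4"), "lin"), 1)
  expect_error(set_similarity(f$idx, f$ic, character(0), "T:4"),
               class = "obokit_empty_set")
  # hand-computed asymmetric-size case: A={T:3,T:4}, B={T:2}
  lin <- function(a, b) term_similarity(f$idx, f$ic, a, b, "lin")
  expect_equal(set_similarity(f$idx, f$ic, c("T:3", "T:4"), "T:2", "lin"),
               0.5 * (mean(c(lin("T:3", "T:2"), lin("T:4", "T:2"))) +
                      max(lin("T:3", "T:2"), lin("T:4", "T:2"))))
})

test_that("similarity laws hold on random corpora", {
  set.seed(11)
  for (seed in 1:3) {
    idx <- build_index(random_dag(30, 2, seed = seed))
    tab <- propagate_annotations(
      idx, random_annotations(idx, 15, 3, seed = seed + 50))
    ic <- information_content(idx, tab)
    terms <- names(ic$ic)
    for (i in 1:60) {
      t1 <- sample(terms, 1); t2 <- sample(terms, 1)
      r <- term_similarity(idx, ic, t1, t2, "resnik")
      l <- term_similarity(idx, ic, t1, t2, "lin")
      expect_gte(r, 0)
      expect_gte(l, 0); expect_lte(l, 1)
      expect_equal(r, term_similarity(idx, ic, t2, t1, "resnik"))
      expect_equal(l, term_similarity(idx, ic, t2, t1, "lin"))
      # self-comparison maximizes resnik over partners
      expect_gte(term_similarity(idx, ic, t1, t1, "resnik"), r)
      if (ic$ic[[t1]] > 0) {
        expect_equal(term_similarity(idx, ic, t1, t1, "lin"), 1)
      }
    }
  }
})

test_that("pairwise matrices are symmetric and identical across cache modes", {
  idx <- build_index(random_dag(40, 2, seed = 3))
  tab <- propagate_annotations(idx, random_annotations(idx, 12, 4, seed = 4))
  ic <- information_content(idx, tab)
  modes <- c("none", "term_matrix", "set_matrix", "lookup_index")
  for (method in c("lin", "resnik")) {
    ms <- lapply(modes, function(cm) {
      pairwise_set_matrix(idx, ic, tab$terms_of, method = method, cache_mode = cm)
    })
    expect_identical(ms[[1]], t(ms[[1]]))
    for (k in 2:4) {
      expect_lt(max(abs(ms[[1]] - ms[[k]])), 1e-12)
    }
  }
  one <- pairwise_set_matrix(idx, ic, tab$terms_of[1], cache_mode = "term_matrix")
  expect_equal(dim(one), c(1L, 1L))
})

test_that("group similarity is the mean over unordered pairs", {
  f <- diamond_ic_fixture()
  m <- pairwise_set_matrix(f$idx, f$ic, f$tab$terms_of)
  expect_equal(group_similarity(m, c(1, 2)), m[1, 2])
  expect_equal(group_similarity(m, 1:3), mean(c(m[1, 2], m[1, 3], m[2, 3])))
  expect_equal(group_similarity(m, c("X", "Y")), m["X", "Y"])
  expect_error(group_similarity(m, 1), class = "obokit_degenerate_group")
  expect_error(group_similarity(m, c(1, 1)), class = "obokit_degenerate_group")
  const <- matrix(0.7, 5, 5)
  expect_equal(group_similarity(const, c(2, 4, 5)), 0.7)
})

test_that("sim_p obeys its bounds, exchangeability and determinism", {
  const <- matrix(0.3, 6, 6, dimnames = list(letters[1:6], letters[1:6]))
  r <- sim_p(const, 1:3, n_permutations = 200, seed = 5)
  expect_equal(r$p_value, 1)
  expect_gte(r$p_value, 1 / (r$n_permutations + 1))

  idx <- build_index(random_dag(30, 2, seed = 8))
  tab <- propagate_annotations(idx, random_annotations(idx, 10, 3, seed = 9))
  m <- pairwise_set_matrix(idx, ic = information_content(idx, tab),
                           sets = tab$terms_of, cache_mode = "lookup_index")
  a <- sim_p(m, 1:3, n_permutations = 500, seed = 21)
  b <- sim_p(m, 1:3, n_permutations = 500, seed = 21)
  expect_identical(a, b)
  expect_equal(a$seed, 21)
  expect_error(sim_p(m, 1:10, seed = 1), class = "obokit_degenerate_null")
})

test_that("a planted cluster yields a small permutation p-value", {
  idx <- build_index(random_dag(60, 2, seed = 13))
  tab <- propagate_annotations(
    idx, random_annotations(idx, 20, 2, planted_group = 5, seed = 14))
  ic <- information_content(idx, tab)
  m <- pairwise_set_matrix(idx, ic, tab$terms_of, cache_mode = "lookup_index")
  r <- sim_p(m, 1:5, n_permutations = 1000, seed = 15)
  expect_lt(r$p_value, 0.05)
})

test_that("Monte-Carlo p agrees with exhaustive enumeration on a tiny population", {
  idx <- build_index(random_dag(25, 2, seed = 31))
  tab <- propagate_annotations(idx, random_annotations(idx, 8, 3, seed = 32))
  m <- pairwise_set_matrix(idx, ic = information_content(idx, tab),
                           sets = tab$terms_of, cache_mode = "lookup_index")
  exact <- exact_sim_p(m, 1:3)
  r <- sim_p(m, 1:3, n_permutations = 5000, seed = 33)
  se <- sqrt(exact * (1 - exact) / 5000)
  expect_lt(abs(r$p_value - exact), 3 * se + 1 / 5001)
})

test_that("results serialize to the documented TSV shapes", {
  const <- matrix(0.25, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  r <- sim_p(const, 1:2, n_permutations = 9, seed = 2)
  lines <- write_sim_p(r)
  expect_equal(lines[1], "statistic\tp_value\tn_permutations\tseed")
  expect_equal(lines[2], "0.250000\t1\t9\t2")
  mat_lines <- write_matrix(const)
  expect_equal(mat_lines[1], "\ta\tb\tc")
  expect_equal(mat_lines[2], "a\t0.250000\t0.250000\t0.250000")
})
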