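test_that("hypergeometric tail probabilities match closed forms and brute force", {
  universe <- sprintf("U%02d", 1:20)
  term <- universe[1:5]
  # full containment: p = 1 / C(20,5)
  enr <- hypergeometric_enrichment(term, list(t = term), universe)
  expect_equal(enr$p_value, 1 / choose(20, 5), tolerance = 1e-12)
  # disjoint: overlap 0 has p = 1
  enr0 <- hypergeometric_enrichment(universe[6:10], list(t = term), universe)
  expect_equal(enr0$p_value, 1)
  # brute-force tail sums over random configurations
  set.seed(8)
  for (i in 1:50) {
    U <- sample(15:60, 1)
    uni <- sprintf("X%03d", 1:U)
    tm <- sample(uni, sample(2:10, 1))
    q <- sample(uni, sample(2:12, 1))
    got <- hypergeometric_enrichment(q, list(t = tm), uni)$p_value
    ov <- length(intersect(q, tm))
    expect_equal(got, hyper_tail(ov, length(tm), U, length(q)),
                 tolerance = 1e-10)
  }
})

test_that("enrichment agrees with exhaustive enumeration of all queries", {
  uni <- sprintf("E%02d", 1:10)
  term <- uni[c(1, 4, 7, 9)]
  combos <- utils::combn(10, 3)
  for (j in seq_len(ncol(combos))) {
    q <- uni[combos[, j]]
    got <- hypergeometric_enrichment(q, list(t = term), uni)$p_value
    ov <- length(intersect(q, term))
    # enumerate: fraction of all C(10,3) queries with overlap >= observed
    allov <- vapply(seq_len(ncol(combos)), function(k)
      length(intersect(uni[combos[, k]], term)), integer(1))
    expect_equal(got, mean(allov >= ov), tolerance = 1e-12)
  }
})

test_that("p-values under random queries are super-uniform", {
  set.seed(14)
  uni <- sprintf("R%03d", 1:100)
  terms <- lapply(1:20, function(i) sample(uni, 15))
  names(terms) <- paste0("T", 1:20)
  p <- unlist(lapply(1:200, function(i)
    hypergeometric_enrichment(sample(uni, 10), terms, uni)$p_value))
  ks <- suppressWarnings(stats::ks.test(p, "punif", alternative = "greater"))
  expect_gt(ks$p.value, 0.01)
})

test_that("relevancy scoring counts significant terms at the q gate", {
  res <- data.frame(term = paste0("T", 1:4), q_value = c(0.01, 0.04, 0.9, 0.2))
  sc <- score_relevancy(res)
  expect_equal(sc$n_significant_terms, 2L)
  expect_equal(sc$best_neg_log10_q, -log10(0.01))
  expect_equal(score_relevancy(data.frame(term = "T", q_value = 0.9))$n_significant_terms, 0L)
  expect_error(hypergeometric_enrichment(character(), list(t = "A"), "A"),
               "empty query")
})

fake_candidate <- function(acc, rel, size, threshold = 0, strategy = "none",
                           id = "cfg") {
  structure(list(
    config = list(id = id,
                  imputation = imputation_spec(strategy, threshold)),
    outer_accuracy = acc,
    relevancy = list(n_significant_terms = rel, best_neg_log10_q = rel),
    final_features = sprintf("%s_f%03d", id, seq_len(size))),
    class = "candidate_result")
}

test_that("best-candidate rule is lexicographic in accuracy, imputation, relevancy, size", {
  a <- fake_candidate(0.90, 2, 50, id = "a")
  b <- fake_candidate(0.90, 3, 60, id = "b")
  expect_identical(select_best_candidate(list(a, b), "transcriptomic")$config$id, "b")
  c1 <- fake_candidate(0.90, 3, 60, id = "c1")
  c2 <- fake_candidate(0.90, 3, 33, id = "c2")
  expect_identical(select_best_candidate(list(c1, c2), "transcriptomic")$config$id, "c2")
  # proteomic: least imputation beats relevancy and size at equal accuracy
  d1 <- fake_candidate(0.95, 9, 10, threshold = 10, strategy = "median", id = "d1")
  d2 <- fake_candidate(0.95, 0, 90, threshold = 0, strategy = "none", id = "d2")
  expect_identical(select_best_candidate(list(d1, d2), "proteomic")$config$id, "d2")
  # accuracy dominates everything
  e1 <- fake_candidate(0.96, 0, 90, threshold = 10, strategy = "zero", id = "e1")
  expect_identical(select_best_candidate(list(d1, d2, e1), "proteomic")$config$id, "e1")
  expect_error(select_best_candidate(list(), "proteomic"), "empty candidate")
})

test_that("the selection rule is a total order: winner invariant to list order", {
  set.seed(23)
  cands <- lapply(1:8, function(i)
    fake_candidate(sample(c(0.8, 0.9), 1), sample(0:3, 1), sample(10:60, 1),
                   threshold = sample(c(0, 5, 10), 1),
                   strategy = sample(c("none", "median", "zero"), 1),
                   id = sprintf("c%02d", i)))
  base <- select_best_candidate(cands, "proteomic")$config$id
  for (r in 1:10) {
    perm <- sample(cands)
    expect_identical(select_best_candidate(perm, "proteomic")$config$id, base)
  }
})
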