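test_that("matching status is the participant-in-both-omics relation", {
  # all matched
  s <- census_samples(c(3, 3, 3), c(0, 0, 0), c(0, 0, 0))
  p <- split_by_matching(s)
  expect_true(all(p$samples$subset == "matched"))
  # disjoint participants: nothing matched
  s2 <- census_samples(c(0, 0, 0), c(3, 3, 3), c(3, 3, 3))
  p2 <- split_by_matching(s2)
  expect_true(all(p2$samples$subset == "unmatched"))
  # duplicate sample for a participant within one omics is a data error
  s3 <- census_samples(c(2, 2, 2), c(0, 0, 0), c(0, 0, 0))
  s3 <- rbind(s3, data.frame(sample_id = "Rdup", participant_id = "M0001",
                             class_label = "AH", tissue = "liver",
                             omics_tag = "transcriptomic"))
  expect_error(split_by_matching(s3), "more than one")
})

test_that("the liver census structure is reproduced from a participant table", {
  # matched per class (both omics): 29, 3, 5; unmatched rna 3,5,3; prot 4,7,5
  s <- census_samples(matched = c(29, 3, 5), unmatched_rna = c(3, 5, 3),
                      unmatched_prot = c(4, 7, 5))
  counts <- partition_counts(split_by_matching(s))
  prot <- counts[counts$omics_tag == "proteomic", ]
  rna <- counts[counts$omics_tag == "transcriptomic", ]
  expect_equal(prot$full[match(c("AH", "CT", "AC"), prot$class_label)],
               c(33L, 10L, 10L))
  expect_equal(prot$matched[match(c("AH", "CT", "AC"), prot$class_label)],
               c(29L, 3L, 5L))
  expect_equal(rna$full[match(c("AH", "CT", "AC"), rna$class_label)],
               c(32L, 8L, 8L))
  expect_equal(rna$unmatched[match(c("AH", "CT", "AC"), rna$class_label)],
               c(3L, 5L, 3L))
})

test_that("rebalancing conserves counts and moves matched pairs jointly", {
  s <- census_samples(matched = c(29, 3, 5), unmatched_rna = c(3, 5, 3),
                      unmatched_prot = c(4, 7, 5))
  part <- split_by_matching(s)
  out <- rebalance(part, min_unmatched_per_class = 7, seed = 11)
  cc <- partition_counts(out$partition)
  expect_true(all(cc$full == cc$matched_balanced + cc$unmatched_balanced))
  # joint movement: both samples of every moved participant changed subset
  sb <- out$partition$samples
  for (pp in out$ledger$participant_id) {
    rows <- sb[sb$participant_id == pp, ]
    expect_equal(nrow(rows), 2L)
    expect_true(all(rows$subset == "matched" & rows$subset_balanced == "unmatched"))
  }
  # deterministic under seed
  out2 <- rebalance(part, 7, seed = 11)
  expect_identical(out$ledger, out2$ledger)
  expect_false(identical(out$ledger, rebalance(part, 7, seed = 12)$ledger))
})

test_that("rebalancing is the identity when every unmatched pool is large enough", {
  s <- census_samples(matched = c(5, 5, 5), unmatched_rna = c(8, 8, 8),
                      unmatched_prot = c(8, 8, 8))
  part <- split_by_matching(s)
  out <- rebalance(part, min_unmatched_per_class = 7, seed = 1)
  expect_equal(nrow(out$ledger), 0L)
  expect_identical(out$partition$samples$subset,
                   out$partition$samples$subset_balanced)
})

test_that("conservation holds after rebalancing random partitions", {
  set.seed(42)
  for (rep in 1:10) {
    m <- sample(2:15, 3); ur <- sample(0:10, 3); up <- sample(0:10, 3)
    part <- split_by_matching(census_samples(m, ur, up))
    out <- rebalance(part, sample(0:9, 1), seed = rep)
    cc <- partition_counts(out$partition)
    expect_true(all(cc$full == cc$matched_balanced + cc$unmatched_balanced))
    expect_true(all(cc$full == cc$matched + cc$unmatched))
    # moved k of m leaves m - k matched-balanced, per class and omics
    moved <- table(factor(out$ledger$class_label, ald_classes()))
    for (i in 1:3) {
      cl <- ald_classes()[i]
      rows <- cc[cc$class_label == cl, ]
      expect_equal(rows$matched_balanced, rows$matched - as.integer(moved[cl]))
    }
  }
})

test_that("verify_conservation reports exact per-class pass/fail", {
  r <- verify_conservation(c(AH = 33, CT = 10, AC = 10),
                           c(AH = 24, CT = 3, AC = 3),
                           c(AH = 9, CT = 7, AC = 7))
  expect_true(all(r$pass))
  r2 <- verify_conservation(10, 4, 5)
  expect_false(r2$pass)
  expect_equal(r2$deficit, 1L)
})

test_that("the shipped study census satisfies both conservation identities", {
  census <- ald_matching_counts()
  expect_equal(nrow(census), 12L)
  expect_true(all(census$full == census$matched + census$unmatched))
  r <- verify_conservation(census$full, census$matched_balanced,
                           census$unmatched_balanced)
  expect_true(all(r$pass))
})
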