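test_that("vectorized rank test agrees with kruskal.test feature by feature", {
  fm <- rand_counts(50, 24, seed = 8)          # counts give plenty of ties
  y <- balanced_labels(8)
  sc <- de_test(fm, y)
  for (i in seq_len(nrow(fm))) {
    ref <- kruskal.test(as.numeric(fm[i, ]), factor(y))
    row <- sc[sc$feature_id == rownames(fm)[i], ]
    expect_equal(row$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(row$p_value, unname(ref$p.value), tolerance = 1e-12)
  }
})

test_that("a constant feature is assigned p = 1; q-values are BH over features", {
  v <- rbind(const = rep(5, 12), varying = c(1:12))
  colnames(v) <- paste0("s", 1:12)
  sc <- de_test(feature_matrix(v, "proteomic"), balanced_labels(4))
  expect_equal(sc$p_value[sc$feature_id == "const"], 1)
  expect_equal(sc$q_value, bh_adjust(sc$p_value))
})

test_that("a fully separating feature attains the maximal permutation statistic", {
  # 3 classes x 4 samples with non-overlapping ranges
  set.seed(1)
  v <- rbind(sep = c(1:4, 11:14, 21:24),
             matrix(rnorm(5 * 12, 50, 5), 5, 12,
                    dimnames = list(paste0("n", 1:5), NULL)))
  colnames(v) <- paste0("s", 1:12)
  y <- balanced_labels(4)
  sc <- de_test(feature_matrix(round(v), "proteomic"), y)
  expect_equal(sc$feature_id[which.min(sc$p_value)], "sep")
  # exact permutation oracle over all 12!/(4!4!4!) = 34650 assignments of
  # ranks 1..12 to groups: the separated feature's statistic is the maximum
  kw_from_sums <- function(s1, s2) {
    s3 <- sum(1:12) - s1 - s2
    12 / (12 * 13) * (s1^2 + s2^2 + s3^2) / 4 - 3 * 13
  }
  obs <- kw_from_sums(sum(1:4), sum(5:8))
  best <- -Inf
  cmb1 <- utils::combn(12, 4)
  for (a in seq_len(ncol(cmb1))) {
    g1 <- cmb1[, a]
    cmb2 <- utils::combn(setdiff(1:12, g1), 4)
    best <- max(best, kw_from_sums(sum(g1), colSums(cmb2)))
  }
  expect_equal(obs, best, tolerance = 1e-9)
  # and the chi-square p of that maximal statistic is the minimal
  # achievable p at this design, attained by the separating feature
  expect_equal(min(sc$p_value), pchisq(best, 2, lower.tail = FALSE),
               tolerance = 1e-9)
})

test_that("label permutations give uniform p-values and no BH discoveries", {
  fm <- rand_counts(200, 30, seed = 13)
  y <- balanced_labels(10)
  set.seed(3)
  pooled <- unlist(lapply(1:20, function(i) de_test(fm, sample(y))$p_value))
  frac_disc <- mean(unlist(lapply(1:20, function(i)
    de_test(fm, sample(y))$q_value <= 0.05)))
  expect_lt(frac_disc, 0.002)
  # crude uniformity: decile occupancy within a generous band
  h <- hist(pooled, breaks = seq(0, 1, 0.1), plot = FALSE)$counts
  expect_true(all(h > 0.5 * length(pooled) / 10))
})

test_that("BH step-up matches the reference implementation and hand cases", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_adjust(0.37), 0.37)
  set.seed(21)
  for (i in 1:1000) {
    p <- runif(sample(1:100, 1))^sample(1:3, 1)
    expect_lt(max(abs(bh_adjust(p) - p.adjust(p, "BH"))), 1e-12)
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("information gain spans 0 to H(labels) with entropy arithmetic", {
  y <- balanced_labels(4)
  v <- rbind(const = rep(1, 12), perfect = c(1:4, 11:14, 21:24))
  colnames(v) <- paste0("s", 1:12)
  sc <- information_gain(feature_matrix(v, "proteomic"), y, bins = 3)
  expect_equal(sc$ig_bits[sc$feature_id == "const"], 0)
  expect_equal(sc$ig_bits[sc$feature_id == "perfect"], log2(3), tolerance = 1e-12)
  # IG <= H(labels) over all 3-class assignments of 6 samples
  set.seed(2)
  x <- matrix(rnorm(6), 1, 6, dimnames = list("f", paste0("s", 1:6)))
  fmx <- feature_matrix(round(x * 10 + 50), "proteomic")
  grid <- expand.grid(rep(list(1:3), 6))
  for (r in seq_len(nrow(grid))) {
    lab <- ald_classes()[as.integer(grid[r, ])]
    if (length(unique(lab)) < 2) next
    H <- -sum(prop.table(table(lab)) * log2(prop.table(table(lab))))
    expect_lte(information_gain(fmx, lab, bins = 2)$ig_bits, H + 1e-12)
  }
  expect_error(information_gain(fmx, rep("AH", 6), 2), "constant labels")
})

test_that("top-k selection ranks, tie-breaks by id, and flags shortfalls", {
  sc <- de_test(rand_counts(20, 12, seed = 4), balanced_labels(4))
  got <- select_top(sc, selection_config("DE", size = 5, q_threshold = 1))
  expect_length(got, 5L)
  expect_equal(got, sc$feature_id[order(sc$p_value, sc$feature_id)][1:5],
               ignore_attr = TRUE)
  # shortfall: a strict q gate at this n keeps nothing
  short <- select_top(sc, selection_config("DE", 10, q_threshold = 1e-6))
  expect_length(short, 0L)
  expect_true(attr(short, "shortfall"))
  # equal scores sort by id
  v <- rbind(zz = c(1, 2, 3, 1, 2, 3), aa = c(1, 2, 3, 1, 2, 3))
  colnames(v) <- paste0("s", 1:6)
  ig <- information_gain(feature_matrix(v, "proteomic"),
                         balanced_labels(2), 2)
  expect_equal(select_top(ig, selection_config("IG", 2))[1], "aa")
  expect_error(select_top(ig, selection_config("DE", 2)), "method")
  expect_error(selection_config("DE", 0), "size")
})

test_that("selection sees only the training subset (mutation check)", {
  fm <- rand_counts(100, 30, seed = 17)
  y <- balanced_labels(10)
  train <- 1:18
  cfg <- selection_config("DE", 10, q_threshold = 1)
  pick1 <- select_top(de_test(fm_subset(fm, samples = train), y[train]), cfg)
  mutated <- unclass(fm)
  mutated[, 19:30] <- matrix(rpois(100 * 12, 500), 100, 12)
  fm2 <- feature_matrix(mutated, "transcriptomic")
  pick2 <- select_top(de_test(fm_subset(fm2, samples = train), y[train]), cfg)
  expect_identical(pick1, pick2)
})

test_that("planted features dominate the selection at moderate effect size", {
  rec <- vapply(1:3, function(s) {
    b <- generate_cohort(cohort_params(n_per_class = 20, n_genes = 500,
                                       n_proteins = 40, n_de_genes = 25,
                                       n_de_proteins = 5, effect_log2fc = 2,
                                       n_matched_pairs = 3, seed = 400 + s))
    y <- b$samples$class_label[match(colnames(b$rna), b$samples$sample_id)]
    sel <- select_top(de_test(b$rna, y), selection_config("DE", 25))
    mean(sel %in% b$truth$genes)
  }, numeric(1))
  expect_gte(mean(rec), 0.8)
})
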