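test_that("confusion matrix counts and accuracy are exact", {
  perfect <- confusion_and_accuracy(balanced_labels(3), balanced_labels(3))
  expect_equal(perfect$accuracy, 1)
  expect_true(all(perfect$confusion[upper.tri(perfect$confusion)] == 0))

  cm <- confusion_and_accuracy(c("AH", "AH", "CT"), c("AH", "CT", "CT"))
  expect_equal(cm$accuracy, 2 / 3)
  expect_equal(cm$confusion["AH", "CT"], 1L)
  expect_equal(sum(cm$confusion), 3L)

  perm <- sample(9)
  y <- balanced_labels(3); p <- rev(y)
  expect_equal(confusion_and_accuracy(y[perm], p[perm])$accuracy,
               confusion_and_accuracy(y, p)$accuracy)
  expect_error(confusion_and_accuracy(c("AH", "ZZ"), c("AH", "AH")),
               "unknown class")
})

rand_probs <- function(n, seed = 1) {
  set.seed(seed)
  p <- matrix(rexp(n * 3), n, 3)
  p <- p / rowSums(p)
  colnames(p) <- ald_classes()
  p
}

test_that("micro-averaged OVR AUC spans the trivial anchors", {
  y <- balanced_labels(4)
  ideal <- diag(3)[as.integer(factor(y, ald_classes())), ]
  colnames(ideal) <- ald_classes()
  soft <- 0.94 * ideal + 0.02   # strictly ordered, rows sum to 1
  expect_equal(micro_ovr_roc(y, soft)$auc, 1.0)
  flat <- matrix(1 / 3, 12, 3, dimnames = list(NULL, ald_classes()))
  expect_equal(micro_ovr_roc(y, flat)$auc, 0.5)
})

test_that("AUC equals pairwise concordance and the reference implementation", {
  for (s in 1:10) {
    y <- sample(balanced_labels(7))[1:20]
    if (length(unique(y)) < 2) next
    p <- rand_probs(20, seed = s)
    got <- micro_ovr_roc(y, p)$auc
    ind <- as.numeric(vapply(ald_classes(), function(cl) y == cl,
                             logical(20)))
    expect_equal(got, concordance_auc(ind, as.numeric(p)), tolerance = 1e-10)
    ref <- as.numeric(pROC::auc(pROC::roc(ind, as.numeric(p), quiet = TRUE,
                                          direction = "<")))
    expect_equal(got, ref, tolerance = 1e-10)
  }
})

test_that("AUC is invariant under row-sum-preserving monotone transforms", {
  y <- balanced_labels(6)
  p <- rand_probs(18, seed = 4)
  base <- micro_ovr_roc(y, p)$auc
  for (cc in c(0.1, 1, 7)) {
    expect_equal(micro_ovr_roc(y, (p + cc) / (1 + 3 * cc))$auc, base,
                 tolerance = 1e-12)
  }
  expect_error(micro_ovr_roc(y, p * 1.3), "sum to 1")
})

test_that("external validation with frozen statistics transfers across cohorts", {
  p <- cohort_params(n_per_class = 30, n_genes = 200, n_proteins = 40,
                     n_de_genes = 20, n_de_proteins = 5, effect_log2fc = 2.5,
                     n_matched_pairs = 3, seed = 71)
  b <- generate_cohort(p)
  y <- b$samples$class_label[match(colnames(b$rna), b$samples$sample_id)]
  # split the cohort into an internal half and an exchangeable external half
  set.seed(1)
  internal <- sort(unlist(lapply(split(seq_along(y), y), sample, 15)))
  external <- setdiff(seq_along(y), internal)
  cfg <- pipeline_config(selection_config("IG", 20), classifier = "LR",
                         hyper_grid = 1)
  fit <- fit_pipeline(fm_subset(b$rna, samples = internal), y[internal], cfg)
  # identity: the training set evaluates to the training metrics
  self <- external_validation(fit, fm_subset(b$rna, samples = internal),
                              y[internal])
  pr <- predict(fit, fm_subset(b$rna, samples = internal), type = "class")
  expect_equal(self$accuracy, mean(pr == y[internal]))
  expect_equal(length(self$dropped_features), 0L)
  # held-out exchangeable samples classify well with frozen statistics
  ext <- external_validation(fit, fm_subset(b$rna, samples = external),
                             y[external])
  expect_gte(ext$accuracy, 0.7)
})

test_that("missing external features trigger refusal or logged dropping", {
  b <- small_bundle(seed = 73, n_per_class = 8)
  y <- b$samples$class_label[match(colnames(b$rna), b$samples$sample_id)]
  fit <- fit_pipeline(b$rna, y,
                      pipeline_config(selection_config("IG", 10),
                                      classifier = "SVM-linear", hyper_grid = 1))
  drop_some <- fm_subset(b$rna,
                         features = setdiff(rownames(b$rna), fit$features[1:2]))
  expect_error(external_validation(fit, drop_some, y), "intersection")
  ok <- external_validation(fit, drop_some, y, intersection = TRUE)
  expect_setequal(intersect(ok$dropped_features, fit$features),
                  fit$features[1:2])
  # fewer than half the panel present: refuse even in intersection mode
  drop_most <- fm_subset(b$rna,
                         features = setdiff(rownames(b$rna),
                                            fit$features[1:8]))
  expect_error(external_validation(fit, drop_most, y, intersection = TRUE),
               "refusing")
})
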