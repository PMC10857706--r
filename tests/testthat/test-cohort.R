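test_that("cohort dimensions and metadata are forced by the parameters", {
  b <- generate_cohort(cohort_params(n_per_class = 10, n_genes = 50,
                                     n_proteins = 40, n_de_genes = 5,
                                     n_de_proteins = 5, n_matched_pairs = 3,
                                     seed = 2))
  s <- b$samples
  expect_equal(sum(s$omics_tag == "transcriptomic"), 30L)
  expect_equal(sum(s$omics_tag == "proteomic"), 30L)
  expect_equal(unname(table(s$class_label[s$omics_tag == "transcriptomic"])),
               rep(10L, 3), ignore_attr = TRUE)
  # every matrix column appears exactly once in the table
  expect_setequal(colnames(b$rna), s$sample_id[s$omics_tag == "transcriptomic"])
  expect_setequal(colnames(b$prot), s$sample_id[s$omics_tag == "proteomic"])
  # matched participants have exactly one sample per omics
  for (p in b$matches$participant_id) {
    expect_equal(sum(s$participant_id == p), 2L)
  }
  # truth is a subset of the feature ids
  expect_true(all(b$truth$genes %in% rownames(b$rna)))
  expect_true(all(b$truth$proteins %in% rownames(b$prot)))
  # counts are integer, non-negative, complete
  expect_false(anyNA(b$rna))
  expect_true(all(b$rna >= 0 & b$rna == round(b$rna)))
})

test_that("fixed seed gives bit-identical bundles; different seeds differ", {
  p <- cohort_params(n_per_class = 6, frac_matched = 0.5,
                     n_genes = 40, n_proteins = 30,
                     n_de_genes = 4, n_de_proteins = 4, n_matched_pairs = 2,
                     seed = 5)
  b1 <- generate_cohort(p); b2 <- generate_cohort(p)
  expect_identical(b1, b2)
  p3 <- p; p3$seed <- 6
  expect_false(identical(generate_cohort(p3)$rna, b1$rna))
})

test_that("planted genes show the requested log2 fold change", {
  b <- generate_cohort(cohort_params(n_per_class = 200, n_genes = 60,
                                     n_proteins = 30, n_de_genes = 30,
                                     n_de_proteins = 5, effect_log2fc = 2,
                                     mcar_rate = 0, mnar_strength = 0,
                                     n_matched_pairs = 3, seed = 31))
  y <- b$samples$class_label[match(colnames(b$rna), b$samples$sample_id)]
  # affected class cycles AH,CT,AC over the sorted planted ids
  lfc <- vapply(seq_along(b$truth$genes), function(j) {
    g <- b$truth$genes[j]
    cl <- ald_classes()[(j - 1) %% 3 + 1]
    log2(mean(b$rna[g, y == cl]) / mean(b$rna[g, y != cl]))
  }, numeric(1))
  se <- sd(lfc) / sqrt(length(lfc))
  expect_lt(abs(mean(lfc) - 2), 2 * se + 0.1)
})

test_that("a null cohort produces essentially no BH discoveries", {
  fractions <- vapply(1:5, function(s) {
    b <- generate_cohort(cohort_params(n_per_class = 100, n_genes = 300,
                                       n_proteins = 30, n_de_genes = 20,
                                       n_de_proteins = 5, effect_log2fc = 0,
                                       n_matched_pairs = 3, seed = 100 + s))
    y <- b$samples$class_label[match(colnames(b$rna), b$samples$sample_id)]
    sc <- de_test(b$rna, y)
    mean(sc$q_value <= 0.05)
  }, numeric(1))
  expect_lt(mean(fractions), 0.01)
})

test_that("missingness injection matches its nominal rates and MNAR tracks intensity", {
  fm <- rand_prot(1000, 100, seed = 3)
  expect_identical(inject_missingness(fm, 0, 0), fm)

  out <- inject_missingness(fm, 0.1, 0, seed = 4)
  expect_lt(abs(mean(is.na(out)) - 0.1), 0.01)
  # observed entries unchanged, originals discarded where flagged
  expect_equal(unclass(out)[!is.na(out)], unclass(fm)[!is.na(out)],
               ignore_attr = TRUE)

  mn <- inject_missingness(fm, 0, 1.5, seed = 5)
  rate <- rowMeans(is.na(mn))
  intensity <- rowMeans(unclass(fm))
  expect_lt(cor(intensity, rate, method = "spearman"), -0.3)

  expect_error(inject_missingness(fm, 1.2, 0), "mcar_rate")
  expect_error(inject_missingness(mn, 0.1, 0), "already contains missing")
})

test_that("annotation sets over-sample planted features in the signal term", {
  all_f <- sprintf("F%03d", 1:200)
  truth <- all_f[1:20]
  ann <- build_annotation_sets(truth, all_f, n_terms = 10, term_size = 20,
                               seed = 9)
  expect_length(ann, 10L)
  expect_true(all(lengths(ann) > 0))
  enr <- hypergeometric_enrichment(truth, ann, all_f)
  expect_identical(enr$term[1], "signal_term")
  expect_equal(enr$p_value[1], min(enr$p_value))
  expect_error(build_annotation_sets(truth, all_f, 5, 0, 1), "term_size")
  expect_error(build_annotation_sets(truth, all_f, 5, 500, 1), "term_size")
})

test_that("cohort bundles survive a disk round trip through their writers", {
  b <- small_bundle(seed = 12, n_per_class = 6)
  dir <- withr::local_tempdir()
  write_cohort(b, dir)
  expect_equal(unclass(read_feature_matrix(file.path(dir, "rna.tsv"),
                                           "transcriptomic")),
               unclass(b$rna), ignore_attr = TRUE)
  prot <- read_feature_matrix(file.path(dir, "prot.tsv"), "proteomic")
  expect_identical(which(is.na(prot)), which(is.na(b$prot)))
  expect_identical(read_gmt(file.path(dir, "annotations.gmt")), b$annotations)
  expect_identical(read_mapping(file.path(dir, "gene_protein_map.tsv")),
                   b$gene_protein_map)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  expect_identical(sort(truth$truth$genes), sort(b$truth$genes))
})

test_that("invalid cohort parameters are rejected by name", {
  expect_error(cohort_params(n_de_genes = 100, n_genes = 50), "n_de_genes")
  expect_error(cohort_params(mcar_rate = 1), "mcar_rate")
  expect_error(cohort_params(frac_matched = 0.37, n_per_class = 10),
               "frac_matched")
})
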