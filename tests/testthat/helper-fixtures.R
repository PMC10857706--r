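# Shared fixtures, all generated in code.

fm_subset <- omicstack:::fm_subset

# small random proteomic matrix (floats, optional missing entries)
rand_prot <- function(n_feat = 10, n_samp = 8, na_frac = 0, seed = 1) {
  set.seed(seed)
  v <- matrix(round(rnorm(n_feat * n_samp, 20, 3), 4), n_feat, n_samp,
              dimnames = list(sprintf("P%03d", seq_len(n_feat)),
                              sprintf("s%02d", seq_len(n_samp))))
  if (na_frac > 0) v[sample(length(v), round(na_frac * length(v)))] <- NA
  feature_matrix(v, "proteomic")
}

rand_counts <- function(n_feat = 10, n_samp = 9, seed = 1) {
  set.seed(seed)
  v <- matrix(rpois(n_feat * n_samp, 50), n_feat, n_samp,
              dimnames = list(sprintf("G%03d", seq_len(n_feat)),
                              sprintf("s%02d", seq_len(n_samp))))
  feature_matrix(v, "transcriptomic")
}

balanced_labels <- function(n_per_class) rep(ald_classes(), each = n_per_class)

# sample table for a given matched/unmatched census (per class), one tissue
census_samples <- function(matched, unmatched_rna, unmatched_prot,
                           tissue = "liver") {
  rows <- list(); pid <- 0
  for (i in seq_along(ald_classes())) {
    cl <- ald_classes()[i]
    for (j in seq_len(matched[i])) {
      pid <- pid + 1
      part <- sprintf("M%04d", pid)
      rows[[length(rows) + 1]] <- data.frame(
        sample_id = c(paste0("R", part), paste0("P", part)),
        participant_id = part, class_label = cl, tissue = tissue,
        omics_tag = c("transcriptomic", "proteomic"))
    }
    for (j in seq_len(unmatched_rna[i])) {
      pid <- pid + 1
      part <- sprintf("U%04d", pid)
      rows[[length(rows) + 1]] <- data.frame(
        sample_id = paste0("R", part), participant_id = part,
        class_label = cl, tissue = tissue, omics_tag = "transcriptomic")
    }
    for (j in seq_len(unmatched_prot[i])) {
      pid <- pid + 1
      part <- sprintf("V%04d", pid)
      rows[[length(rows) + 1]] <- data.frame(
        sample_id = paste0("P", part), participant_id = part,
        class_label = cl, tissue = tissue, omics_tag = "proteomic")
    }
  }
  do.call(rbind, rows)
}

# brute-force hypergeometric upper tail P[X >= ov]
hyper_tail <- function(ov, term, universe, query) {
  sum(stats::dhyper(ov:min(term, query), term, universe - term, query))
}

# O(n^2) concordance AUC with ties counted 1/2
concordance_auc <- function(y, s) {
  pos <- which(y == 1); neg <- which(y == 0)
  tot <- 0
  for (i in pos) tot <- tot + sum(s[i] > s[neg]) + 0.5 * sum(s[i] == s[neg])
  tot / (length(pos) * length(neg))
}

small_bundle <- function(seed = 7, n_per_class = 15) {
  generate_cohort(cohort_params(
    n_per_class = n_per_class,
    frac_matched = round(0.6 * n_per_class) / n_per_class,
    n_genes = 300, n_proteins = 150,
    n_de_genes = 30, n_de_proteins = 15, effect_log2fc = 2.5,
    n_matched_pairs = 10, seed = seed))
}

small_plan <- function(seed = 3) {
  stage_plan(k_outer = 3, k_inner = 2, k_meta = 3,
             min_unmatched_per_class = 5, seed = seed)
}
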