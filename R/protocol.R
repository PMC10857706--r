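# Orchestration of the three-stage protocol on a cohort bundle:
# Stage 1  nested CV on the full datasets, per omics;
# Stage 2A nested CV on the unmatched-balanced subsets;
#       2B refit the 2A winners on all unmatched-balanced data and test
#          them on the matched-balanced subsets;
#       2C stack the two base models' probabilities on matched
#          participants and cross-validate the integrated meta-model;
# Stage 3  intersect the winning gene and protein panels.
# Every artifact is written with its config id and seed.

#' Plan for a protocol run
#'
#' @param rna_configs,prot_configs Lists of [pipeline_config()]s to grid
#'   over (integration stages require LR or SVM-linear entries).
#' @param k_outer,k_inner NCV fold counts.
#' @param k_meta Folds for the integrated evaluation.
#' @param min_unmatched_per_class Rebalancing floor.
#' @param seed Integer seed.
#' @return A list of class `stage_plan`.
#' @export
stage_plan <- function(rna_configs = list(pipeline_config(
                         selection_config("IG", 50), classifier = "LR",
                         hyper_grid = c(0.1, 1))),
                       prot_configs = list(pipeline_config(
                         selection_config("DE", 25, q_threshold = 1),
                         imputation_spec("median", 10), classifier = "LR",
                         hyper_grid = c(0.1, 1))),
                       k_outer = 5, k_inner = 3, k_meta = 5,
                       min_unmatched_per_class = 7, seed = 1) {
  structure(list(rna_configs = rna_configs, prot_configs = prot_configs,
                 k_outer = k_outer, k_inner = k_inner, k_meta = k_meta,
                 min_unmatched_per_class = min_unmatched_per_class,
                 seed = seed),
            class = "stage_plan")
}

subset_samples <- function(samples, omics, balanced_subset = NULL) {
  s <- samples[samples$omics_tag == omics, ]
  if (!is.null(balanced_subset)) s <- s[s$subset_balanced == balanced_subset, ]
  s
}

#' Run the full three-stage protocol
#'
#' @param bundle A `cohort_bundle` (see [generate_cohort()] or assemble
#'   one from files).
#' @param plan A [stage_plan()].
#' @param out_dir Optional directory; when given, metrics JSON, panel
#'   TSVs and the intersection report are written there.
#' @return List of class `protocol_result` with elements `stage1`,
#'   `stage2a`, `stage2b`, `stage2c`, `stage3`, `partition`.
#' @export
run_protocol <- function(bundle, plan = stage_plan(), out_dir = NULL) {
  seed <- plan$seed
  part <- split_by_matching(bundle$samples)
  reb <- rebalance(part, plan$min_unmatched_per_class,
                   seed = child_seed(seed, 1L))
  samples <- reb$partition$samples

  labels_of <- function(fm) labels_for(fm, samples)
  fm_for <- function(fm, ids) fm_subset(fm, samples = match(ids, colnames(fm)))

  # Stage 1: full datasets
  stage1 <- list(
    rna = run_nested_cv(bundle$rna, labels_of(bundle$rna), plan$rna_configs,
                        plan$k_outer, plan$k_inner, seed = child_seed(seed, 2L)),
    prot = run_nested_cv(bundle$prot, labels_of(bundle$prot), plan$prot_configs,
                         plan$k_outer, plan$k_inner, seed = child_seed(seed, 3L)))

  # Stage 2A: unmatched balanced
  ub_rna_ids <- subset_samples(samples, "transcriptomic", "unmatched")$sample_id
  ub_prot_ids <- subset_samples(samples, "proteomic", "unmatched")$sample_id
  ub_rna <- fm_for(bundle$rna, ub_rna_ids)
  ub_prot <- fm_for(bundle$prot, ub_prot_ids)
  stage2a <- list(
    rna = run_nested_cv(ub_rna, labels_of(ub_rna), plan$rna_configs,
                        plan$k_outer, plan$k_inner, seed = child_seed(seed, 4L)),
    prot = run_nested_cv(ub_prot, labels_of(ub_prot), plan$prot_configs,
                         plan$k_outer, plan$k_inner, seed = child_seed(seed, 5L)))
  universe_rna <- rownames(bundle$rna)
  universe_prot <- rownames(bundle$prot)
  stage2a$rna <- add_relevancy(stage2a$rna, bundle$annotations, universe_rna)
  stage2a$prot <- add_relevancy(stage2a$prot, bundle$annotations, universe_prot)
  win_rna <- select_best_candidate(stage2a$rna, "transcriptomic")
  win_prot <- select_best_candidate(stage2a$prot, "proteomic")

  # Stage 2B: refit winners on all unmatched-balanced, test on matched-balanced
  mb_rna_ids <- subset_samples(samples, "transcriptomic", "matched")$sample_id
  mb_prot_ids <- subset_samples(samples, "proteomic", "matched")$sample_id
  mb_rna <- fm_for(bundle$rna, mb_rna_ids)
  mb_prot <- fm_for(bundle$prot, mb_prot_ids)
  bases <- train_base_models(ub_rna, labels_of(ub_rna),
                             ub_prot, labels_of(ub_prot),
                             win_rna$config, win_prot$config)
  eval_on <- function(base, fm) {
    pr <- predict(base, fm, type = "prob")
    pred <- factor(ALD_CLASSES[max.col(pr, ties.method = "first")],
                   levels = ALD_CLASSES)
    cm <- confusion_and_accuracy(labels_of(fm), pred)
    list(accuracy = cm$accuracy, confusion = cm$confusion, prob = pr)
  }
  stage2b <- list(rna = eval_on(bases$rna_base, mb_rna),
                  prot = eval_on(bases$prot_base, mb_prot))

  # Stage 2C: stack on matched participants, cross-validate the meta-model
  st <- stack_probabilities(bases$rna_base, bases$prot_base,
                            mb_rna, mb_prot, samples)
  stage2c <- evaluate_integrated(st$meta, st$labels, k = plan$k_meta,
                                 seed = child_seed(seed, 6L))
  model <- stacked_model(bases$rna_base, bases$prot_base, st$meta, st$labels)

  # Stage 3: intersect the winning panels
  gene_panel <- win_rna$final_features %||% win_rna$consensus_features
  prot_panel <- win_prot$final_features %||% win_prot$consensus_features
  report <- match_panels(gene_panel, prot_panel, bundle$gene_protein_map)
  sig_genes <- tryCatch({
    sc <- de_test(bundle$rna, labels_of(bundle$rna))
    sc$feature_id[sc$q_value <= 0.05]
  }, error = function(e) character())
  sig_prots <- tryCatch({
    pp <- preprocess_fit(bundle$prot, imputation_spec("median", 10),
                         remove_outliers = FALSE)
    sc <- de_test(pp$matrix, labels_for(pp$matrix, samples))
    sc$feature_id[sc$q_value <= 0.05]
  }, error = function(e) character())
  m <- bundle$gene_protein_map
  pairs_in_sig <- sum(m$gene_id %in% sig_genes & m$protein_id %in% sig_prots)
  exp_shared <- if (length(sig_genes) > 0 && length(sig_prots) > 0) {
    expected_shared(min(length(gene_panel), length(sig_genes)),
                    length(sig_genes),
                    min(length(prot_panel), length(sig_prots)),
                    length(sig_prots), pairs_in_sig)
  } else NA_real_
  stage3 <- list(report = report, expected_shared = exp_shared,
                 gene_panel = gene_panel, protein_panel = prot_panel,
                 n_sig_genes = length(sig_genes),
                 n_sig_proteins = length(sig_prots))

  out <- structure(list(partition = reb, stage1 = stage1, stage2a = stage2a,
                        winners = list(rna = win_rna, prot = win_prot),
                        stage2b = stage2b, stage2c = stage2c,
                        model = model, stage3 = stage3, plan = plan),
                   class = "protocol_result")
  if (!is.null(out_dir)) write_protocol(out, out_dir)
  out
}

#' @export
print.protocol_result <- function(x, ...) {
  cat("<protocol_result>\n")
  cat(sprintf("  stage1  full NCV:        rna %.3f, prot %.3f\n",
              x$stage1$rna[[1]]$outer_accuracy, x$stage1$prot[[1]]$outer_accuracy))
  cat(sprintf("  stage2a unmatched NCV:   rna %.3f, prot %.3f (winners %s / %s)\n",
              x$winners$rna$outer_accuracy, x$winners$prot$outer_accuracy,
              x$winners$rna$config$id, x$winners$prot$config$id))
  cat(sprintf("  stage2b matched test:    rna %.3f, prot %.3f\n",
              x$stage2b$rna$accuracy, x$stage2b$prot$accuracy))
  cat(sprintf("  stage2c integrated CV:   %.3f (AUC %.3f)\n",
              x$stage2c$accuracy, x$stage2c$auc))
  cat(sprintf("  stage3  shared pairs:    %d observed, %.3f expected\n",
              x$stage3$report$observed_shared, x$stage3$expected_shared))
  invisible(x)
}

write_protocol <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  metrics <- list(
    seed = result$plan$seed,
    stage1 = list(rna = lapply(result$stage1$rna, function(r)
                    list(config = r$config$id, accuracy = r$outer_accuracy)),
                  prot = lapply(result$stage1$prot, function(r)
                    list(config = r$config$id, accuracy = r$outer_accuracy))),
    stage2a_winners = list(rna = result$winners$rna$config$id,
                           prot = result$winners$prot$config$id),
    stage2b = list(rna_accuracy = result$stage2b$rna$accuracy,
                   prot_accuracy = result$stage2b$prot$accuracy),
    stage2c = list(accuracy = result$stage2c$accuracy,
                   auc = result$stage2c$auc,
                   reference = lapply(result$stage2c$reference, function(r)
                     list(accuracy = r$accuracy, auc = r$auc))),
    stage3 = list(observed_shared = result$stage3$report$observed_shared,
                  expected_shared = result$stage3$expected_shared,
                  n_sig_genes = result$stage3$n_sig_genes,
                  n_sig_proteins = result$stage3$n_sig_proteins))
  jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(result$stage3$gene_panel, file.path(out_dir, "gene_panel.txt"))
  writeLines(result$stage3$protein_panel, file.path(out_dir, "protein_panel.txt"))
  utils::write.table(result$partition$ledger,
                     file.path(out_dir, "move_ledger.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out_dir)
}
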