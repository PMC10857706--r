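# Late-fusion integration. Base pipelines are trained per omics on the
# unmatched-balanced pool; their class probabilities on matched
# participants are concatenated into 6 meta-features (3 classes x 2
# omics) and a logistic meta-classifier is cross-validated on them. The
# meta-model never sees raw feature matrices, which removes any bias
# toward one platform's feature scale.

#' Train the two per-omics base models
#'
#' Refits the winning configuration of each omics on the entirety of its
#' unmatched-balanced data (the feature-selection procedure is re-run on
#' that data, not a frozen list). Base classifiers are restricted to LR
#' and linear SVM.
#'
#' @param unmatched_rna,unmatched_prot [feature_matrix()] objects
#'   restricted to the unmatched-balanced samples.
#' @param rna_labels,prot_labels Matching label vectors.
#' @param best_rna_config,best_prot_config Winning [pipeline_config()]s.
#' @return List with fitted `rna_base` and `prot_base`
#'   (`omics_pipeline`s).
#' @export
train_base_models <- function(unmatched_rna, rna_labels,
                              unmatched_prot, prot_labels,
                              best_rna_config, best_prot_config) {
  for (cfg in list(best_rna_config, best_prot_config)) {
    if (!cfg$classifier %in% c("LR", "SVM-linear")) {
      stop("integration base classifiers are restricted to LR and SVM-linear")
    }
  }
  rna_base <- fit_pipeline(unmatched_rna, rna_labels, best_rna_config,
                           hyper = best_rna_config$hyper_grid[[1L]])
  prot_base <- fit_pipeline(unmatched_prot, prot_labels, best_prot_config,
                            hyper = best_prot_config$hyper_grid[[1L]])
  if (is.null(rna_base) || is.null(prot_base)) {
    stop("base model selection collapsed to 0 features")
  }
  list(rna_base = rna_base, prot_base = prot_base)
}

#' Stack per-omics class probabilities into meta-features
#'
#' One row per matched participant:
#' `(P_rna(AH), P_rna(CT), P_rna(AC), P_prot(AH), P_prot(CT), P_prot(AC))`.
#' Participants missing either omics sample are excluded (reported in the
#' `excluded` attribute); conflicting class labels across a participant's
#' two samples are a data error.
#'
#' @param rna_base,prot_base Fitted `omics_pipeline`s.
#' @param matched_rna,matched_prot [feature_matrix()] objects holding the
#'   matched-balanced samples.
#' @param samples Sample table covering all matched samples.
#' @return List with `meta` (participants x 6 matrix) and `labels`.
#' @export
stack_probabilities <- function(rna_base, prot_base, matched_rna,
                                matched_prot, samples) {
  samples <- validate_samples(samples)
  part_of <- function(ids) samples$participant_id[match(ids, samples$sample_id)]
  class_of <- function(ids) as.character(samples$class_label[match(ids, samples$sample_id)])
  rna_part <- part_of(colnames(matched_rna))
  prot_part <- part_of(colnames(matched_prot))
  common <- intersect(rna_part, prot_part)
  excluded <- setdiff(union(rna_part, prot_part), common)
  if (length(common) == 0L) stop("no participant has samples in both omics")

  rna_idx <- match(common, rna_part)
  prot_idx <- match(common, prot_part)
  cls_r <- class_of(colnames(matched_rna)[rna_idx])
  cls_p <- class_of(colnames(matched_prot)[prot_idx])
  if (any(cls_r != cls_p)) {
    stop("data error: conflicting class labels for participant ",
         common[cls_r != cls_p][1L])
  }
  p_rna <- predict(rna_base, fm_subset(matched_rna, samples = rna_idx),
                   type = "prob")
  p_prot <- predict(prot_base, fm_subset(matched_prot, samples = prot_idx),
                    type = "prob")
  meta <- cbind(p_rna, p_prot)
  dimnames(meta) <- list(common,
                         c(paste0("rna_", ALD_CLASSES),
                           paste0("prot_", ALD_CLASSES)))
  structure(list(meta = meta, labels = as_ald_factor(cls_r)),
            excluded = excluded)
}

# meta-classifier: LR with default hyperparameters (unit inverse
# regularization), fit on the 6 probability meta-features only
fit_meta <- function(meta, labels) {
  fit_classifier(meta, labels, classifier = "LR", hyper = 1)
}

#' Train a stacked late-fusion model
#'
#' @param rna_base,prot_base Fitted per-omics `omics_pipeline`s.
#' @param meta Meta-feature matrix from [stack_probabilities()].
#' @param labels Participant labels.
#' @return Object of class `stacked_model`.
#' @export
stacked_model <- function(rna_base, prot_base, meta, labels) {
  structure(list(rna_base = rna_base, prot_base = prot_base,
                 meta = fit_meta(meta, labels), classes = ALD_CLASSES),
            class = "stacked_model")
}

#' @export
print.stacked_model <- function(x, ...) {
  cat("<stacked_model> late fusion of:\n  rna:  ")
  print(x$rna_base$model)
  cat("  prot: ")
  print(x$prot_base$model)
  invisible(x)
}

#' Predict from a stacked model
#'
#' @param object A `stacked_model`.
#' @param matched_rna,matched_prot Feature matrices of the participants to
#'   predict (columns aligned participant-wise via `samples`).
#' @param samples Sample table.
#' @param type `"prob"` or `"class"`.
#' @param ... Unused.
#' @export
predict.stacked_model <- function(object, matched_rna, matched_prot, samples,
                                  type = c("prob", "class"), ...) {
  type <- match.arg(type)
  st <- stack_probabilities(object$rna_base, object$prot_base,
                            matched_rna, matched_prot, samples)
  stats::predict(object$meta, st$meta, type = type)
}

#' Cross-validated evaluation of the integrated meta-classifier
#'
#' Stratified k-fold CV on participants: the meta logistic classifier is
#' fit on training meta-rows and evaluated on the held-out rows. On the
#' same folds, single-omics reference classifiers (LR on each omics' own
#' 3-probability block) are evaluated for comparison.
#'
#' @param meta Participants x 6 meta-feature matrix (two 3-column blocks).
#' @param labels Participant labels.
#' @param k Folds (default 5).
#' @param seed Integer seed.
#' @return List with `accuracy`, `confusion`, `auc`, and `reference`
#'   (per-omics accuracy/auc on the same folds).
#' @export
evaluate_integrated <- function(meta, labels, k = 5, seed = 1) {
  y <- as_ald_factor(labels)
  meta <- as.matrix(meta)
  if (ncol(meta) != 6L) stop("meta matrix must have 6 columns (2 x 3 classes)")
  folds <- make_stratified_folds(y, k, seed = seed)
  blocks <- list(integrated = seq_len(6L), rna = 1:3, prot = 4:6)
  prob <- lapply(blocks, function(b)
    matrix(NA_real_, length(y), 3L, dimnames = list(NULL, ALD_CLASSES)))
  for (f in seq_len(attr(folds, "k"))) {
    tr <- which(folds != f); te <- which(folds == f)
    for (nm in names(blocks)) {
      m <- fit_meta(meta[tr, blocks[[nm]], drop = FALSE], y[tr])
      prob[[nm]][te, ] <- stats::predict(
        m, meta[te, blocks[[nm]], drop = FALSE], type = "prob")
    }
  }
  res <- lapply(prob, function(pr) {
    pred <- factor(ALD_CLASSES[max.col(pr, ties.method = "first")],
                   levels = ALD_CLASSES)
    cm <- confusion_and_accuracy(y, pred)
    auc <- tryCatch(micro_ovr_roc(y, pr)$auc, error = function(e) NA_real_)
    list(accuracy = cm$accuracy, confusion = cm$confusion, auc = auc)
  })
  c(res$integrated, list(reference = res[c("rna", "prot")]))
}
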