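# Reporting: confusion matrices, micro-averaged one-vs-rest ROC/AUC,
# linear-model feature importance, and the frozen-statistics external
# validation transfer.

#' Confusion matrix and accuracy
#'
#' Rows are true classes, columns predicted, in canonical order
#' (AH, CT, AC); accuracy is the trace over the total.
#'
#' @param truth,predicted Equal-length label vectors over AH/CT/AC.
#' @return List with `confusion` (3 x 3 integer matrix) and `accuracy`.
#' @export
confusion_and_accuracy <- function(truth, predicted) {
  t_ <- as_ald_factor(truth); p_ <- as_ald_factor(predicted)
  if (length(t_) != length(p_)) stop("label vectors differ in length")
  cm <- table(truth = t_, predicted = p_)
  cm <- matrix(as.integer(cm), 3L, 3L, dimnames = dimnames(cm))
  list(confusion = cm, accuracy = sum(diag(cm)) / sum(cm))
}

#' Micro-averaged one-vs-rest ROC and AUC
#'
#' All (sample, class) pairs are pooled into binary indicators versus
#' their predicted probabilities; a single ROC is computed over the
#' pooled pairs with ties grouped at equal thresholds, and AUC by the
#' trapezoid rule.
#'
#' @param truth Label vector over AH/CT/AC.
#' @param prob n x 3 probability matrix, columns in canonical class order
#'   (named columns are reordered); rows must sum to 1.
#' @return List with `roc` (data frame `threshold`, `fpr`, `tpr`) and
#'   `auc`.
#' @export
micro_ovr_roc <- function(truth, prob) {
  y <- as_ald_factor(truth)
  prob <- as.matrix(prob)
  if (ncol(prob) != 3L) stop("probability matrix must have 3 columns")
  if (!is.null(colnames(prob))) prob <- prob[, ALD_CLASSES, drop = FALSE]
  if (any(abs(rowSums(prob) - 1) > 1e-6)) {
    stop("probability rows must sum to 1")
  }
  ind <- as.numeric(vapply(ALD_CLASSES, function(cl) y == cl, logical(length(y))))
  sc <- as.numeric(prob)
  if (all(ind == ind[1L])) stop("degenerate input: all indicators identical")
  # group ties at equal thresholds
  ord <- order(sc, decreasing = TRUE)
  sc_o <- sc[ord]; ind_o <- ind[ord]
  brk <- c(which(diff(sc_o) != 0), length(sc_o))
  tp <- cumsum(ind_o)[brk]; fp <- cumsum(1 - ind_o)[brk]
  P <- sum(ind); N <- length(ind) - P
  tpr <- c(0, tp / P); fpr <- c(0, fp / N)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(roc = data.frame(threshold = c(Inf, sc_o[brk]), fpr = fpr, tpr = tpr),
       auc = auc)
}

#' Feature importance of a linear model
#'
#' Importance of a feature is the mean absolute coefficient across the
#' three one-vs-rest class vectors on the standardized feature scale,
#' ranked descending with ties broken by feature id.
#'
#' @param model An `omics_classifier` or `omics_pipeline` of type LR or
#'   SVM-linear (kNN and RBF kernels have no coefficient vector and are
#'   rejected).
#' @return Data frame with columns `feature_id`, `importance`, `rank`.
#' @export
feature_importance <- function(model) {
  W <- coef(model)   # errors for unsupported models
  imp <- colMeans(abs(W))
  ord <- order(-imp, names(imp))
  data.frame(feature_id = names(imp)[ord], importance = unname(imp[ord]),
             rank = seq_along(imp), stringsAsFactors = FALSE)
}

#' Evaluate a trained pipeline on an external cohort
#'
#' No refitting: selected features, imputation medians and
#' standardization statistics stay frozen from training. By default every
#' selected feature must be present in the external matrix; with
#' `intersection = TRUE` missing features are dropped (and reported),
#' refused when fewer than `min_feature_frac` survive.
#'
#' @param pipeline A fitted `omics_pipeline`.
#' @param external A [feature_matrix()].
#' @param external_labels Labels for the external samples.
#' @param intersection Allow evaluation on the intersecting feature set.
#' @param min_feature_frac Minimum fraction of selected features that must
#'   be present (default 0.5).
#' @return List with `accuracy`, `confusion`, `auc`, `dropped_features`.
#' @export
external_validation <- function(pipeline, external, external_labels,
                                intersection = FALSE, min_feature_frac = 0.5) {
  y <- as_ald_factor(external_labels)
  present <- intersect(pipeline$prep$features, rownames(external))
  frac <- length(intersect(pipeline$features, rownames(external))) /
    length(pipeline$features)
  if (frac < 1 && !intersection) {
    stop("external matrix lacks ",
         length(setdiff(pipeline$features, rownames(external))),
         " selected feature(s); use intersection = TRUE to drop them")
  }
  if (frac < min_feature_frac) {
    stop(sprintf("only %.0f%% of selected features present (< %.0f%%); refusing",
                 100 * frac, 100 * min_feature_frac))
  }
  dropped <- setdiff(pipeline$prep$features, rownames(external))
  if (length(dropped) > 0L) {
    # neutral fill: absent features sit at their training mean, i.e. 0
    # after standardization, so the frozen model still applies
    pad <- matrix(0, length(dropped), ncol(external),
                  dimnames = list(dropped, colnames(external)))
    centers <- pipeline$model$center
    for (f in dropped) {
      pad[f, ] <- if (f %in% names(centers)) centers[[f]] else 0
    }
    aug <- rbind(unclass(external), pad)
    attr(aug, "omics_tag") <- omics_tag(external)
    class(aug) <- c("feature_matrix", "matrix", "array")
    external <- aug
  }
  prob <- predict(pipeline, external, type = "prob")
  pred <- factor(ALD_CLASSES[max.col(prob, ties.method = "first")],
                 levels = ALD_CLASSES)
  cm <- confusion_and_accuracy(y, pred)
  auc <- tryCatch(micro_ovr_roc(y, prob)$auc, error = function(e) NA_real_)
  list(accuracy = cm$accuracy, confusion = cm$confusion, auc = auc,
       dropped_features = dropped)
}
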