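# Nested cross-validation over pipeline configurations. Feature selection
# and preprocessing are recomputed inside every training split (inner and
# outer), which is what keeps the outer accuracy an honest generalization
# estimate at feature/sample ratios this extreme. A deliberately leaky
# variant (selection once on all data, then plain CV) is provided to
# demonstrate the selection bias the nested design avoids.

#' Stratified k-fold assignment
#'
#' Folds are disjoint, cover every sample, and per-class counts differ by
#' at most one across folds. If some class has fewer than `k` samples, `k`
#' is reduced to the smallest class size with a warning.
#'
#' @param labels Class labels.
#' @param k Number of folds (>= 2).
#' @param seed Integer seed.
#' @return Integer vector of fold ids in `1..k`, with attribute `k`.
#' @export
make_stratified_folds <- function(labels, k, seed = 1) {
  y <- factor(as.character(labels))
  if (k < 2) stop("k must be >= 2")
  smallest <- min(table(y))
  if (smallest < 2L) {
    stop("class ", names(which.min(table(y))), " has a single sample; ",
         "stratified folds are impossible")
  }
  if (smallest < k) {
    warning("reducing k from ", k, " to smallest class size ", smallest)
    k <- smallest
  }
  fold <- integer(length(y))
  with_seed(seed, {
    for (cl in levels(y)) {
      idx <- which(y == cl)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  attr(fold, "k") <- as.integer(k)
  fold
}

#' Nested cross-validation over a configuration grid
#'
#' For each configuration and each outer fold: inner CV on the
#' outer-training set (feature selection recomputed per inner training
#' split) picks the hyperparameter; the pipeline is then refit on the full
#' outer-training set and the outer test fold is predicted once. Outer
#' accuracies and confusion matrices aggregate over folds. Configurations
#' whose selection collapses to zero features are skipped with a warning.
#'
#' @param fm A [feature_matrix()].
#' @param labels Class labels, one per sample column.
#' @param configs A [pipeline_config()] or list of them.
#' @param k_outer,k_inner Fold counts (defaults 5 and 3).
#' @param seed Integer seed driving fold plans.
#' @return List of class `ncv_result`; each element is a
#'   `candidate_result` with `config`, `outer_accuracy`, `confusion`,
#'   `fold_features`, `consensus_features`, `final_features` (selection
#'   re-run on all data), `chosen_hyper` per fold, and `probabilities`
#'   (out-of-fold class probabilities).
#' @export
run_nested_cv <- function(fm, labels, configs, k_outer = 5, k_inner = 3,
                          seed = 1) {
  if (inherits(configs, "pipeline_config")) configs <- list(configs)
  y <- as_ald_factor(labels)
  folds <- make_stratified_folds(y, k_outer, seed = seed)
  k_outer <- attr(folds, "k")

  results <- list()
  for (cfg in configs) {
    pred <- factor(rep(NA_character_, length(y)), levels = ALD_CLASSES)
    prob <- matrix(NA_real_, length(y), 3L,
                   dimnames = list(colnames(fm), ALD_CLASSES))
    fold_features <- vector("list", k_outer)
    chosen <- numeric(k_outer)
    skipped <- FALSE
    for (f in seq_len(k_outer)) {
      tr <- which(folds != f); te <- which(folds == f)
      fm_tr <- fm_subset(fm, samples = tr)
      y_tr <- y[tr]
      hyper <- tune_hyper(fm_tr, y_tr, cfg, k_inner,
                          seed = child_seed(seed, f))
      fit <- fit_pipeline(fm_tr, y_tr, cfg, hyper = hyper)
      if (is.null(fit)) { skipped <- TRUE; break }
      fold_features[[f]] <- fit$features
      chosen[f] <- hyper
      pr <- predict(fit, fm_subset(fm, samples = te), type = "prob")
      prob[te, ] <- pr
      pred[te] <- ALD_CLASSES[max.col(pr, ties.method = "first")]
    }
    if (skipped) {
      warning("config ", cfg$id, " skipped: selection shortfall to 0 features")
      next
    }
    cm <- confusion_and_accuracy(y, pred)
    feats <- unlist(fold_features)
    consensus <- sort(names(which(table(feats) > k_outer / 2)))
    final_features <- tryCatch({
      prep <- preprocess_fit(fm, spec = cfg$imputation,
                             dominance_ratio = cfg$dominance_ratio,
                             remove_outliers = omics_tag(fm) == "transcriptomic")
      run_selection(prep$matrix, y, cfg$selection)
    }, error = function(e) character())
    res <- structure(list(config = cfg, outer_accuracy = cm$accuracy,
                          confusion = cm$confusion,
                          fold_features = fold_features,
                          consensus_features = consensus,
                          final_features = final_features,
                          chosen_hyper = chosen, probabilities = prob,
                          fold_plan = folds, n = length(y)),
                     class = "candidate_result")
    results[[cfg$id]] <- res
  }
  structure(results, class = "ncv_result")
}

# Inner CV: preprocessing and selection recomputed once per inner-training
# split (they do not depend on the classifier hyperparameter), then every
# grid point is fit on the selected features and scored on the inner test
# fold; returns the grid point with the best mean inner accuracy (ties ->
# first grid entry). Degenerate inner splits (a class collapsing to one
# sample) contribute no evidence.
tune_hyper <- function(fm, y, cfg, k_inner, seed = 1) {
  grid <- cfg$hyper_grid
  if (length(grid) == 1L) return(grid[[1L]])
  folds <- suppressWarnings(make_stratified_folds(y, k_inner, seed = seed))
  acc <- matrix(NA_real_, attr(folds, "k"), length(grid))
  for (f in seq_len(attr(folds, "k"))) {
    tr <- which(folds != f); te <- which(folds == f)
    sel <- tryCatch({
      prep <- preprocess_fit(fm_subset(fm, samples = tr),
                             spec = cfg$imputation,
                             dominance_ratio = cfg$dominance_ratio,
                             remove_outliers = omics_tag(fm) == "transcriptomic")
      feats <- run_selection(prep$matrix, y[tr], cfg$selection)
      if (length(feats) == 0L) NULL else list(prep = prep, feats = feats)
    }, error = function(e) NULL)
    if (is.null(sel)) next
    x_tr <- t(unclass(sel$prep$matrix)[sel$feats, , drop = FALSE])
    te_fm <- preprocess_apply(sel$prep, fm_subset(fm, samples = te))
    x_te <- t(unclass(te_fm)[sel$feats, , drop = FALSE])
    for (g in seq_along(grid)) {
      m <- tryCatch(fit_classifier(x_tr, y[tr], cfg$classifier, grid[[g]]),
                    error = function(e) NULL)
      if (is.null(m)) next
      acc[f, g] <- mean(stats::predict(m, x_te, type = "class") == y[te])
    }
  }
  means <- colMeans(acc, na.rm = TRUE)
  if (all(is.nan(means))) return(grid[[1L]])
  grid[[which.max(means)]]
}

#' @export
print.candidate_result <- function(x, ...) {
  cat(sprintf("<candidate_result> %s: outer accuracy %.3f (n = %d)\n",
              x$config$id, x$outer_accuracy, x$n))
  invisible(x)
}

#' @export
print.ncv_result <- function(x, ...) {
  cat("<ncv_result>", length(x), "configuration(s)\n")
  for (r in x) {
    cat(sprintf("  %-28s acc %.3f, %d consensus features\n",
                r$config$id, r$outer_accuracy, length(r$consensus_features)))
  }
  invisible(x)
}

#' Deliberately leaky cross-validation (selection before CV)
#'
#' Runs feature selection once on the full data set and only then
#' cross-validates the classifier on the selected features. This is the
#' classic selection-bias construction: on null data its accuracy estimate
#' exceeds the nested one. Provided for demonstration and calibration
#' checks, never for analysis.
#'
#' @inheritParams run_nested_cv
#' @param config A single [pipeline_config()].
#' @return List with `accuracy` and `features`.
#' @export
run_leaky_cv <- function(fm, labels, config, k_outer = 5, seed = 1) {
  y <- as_ald_factor(labels)
  prep <- preprocess_fit(fm, spec = config$imputation,
                         dominance_ratio = config$dominance_ratio,
                         remove_outliers = omics_tag(fm) == "transcriptomic")
  feats <- run_selection(prep$matrix, y, config$selection)
  if (length(feats) == 0L) stop("selection retained no features")
  x <- t(unclass(prep$matrix)[feats, , drop = FALSE])
  folds <- make_stratified_folds(y, k_outer, seed = seed)
  pred <- factor(rep(NA_character_, length(y)), levels = ALD_CLASSES)
  for (f in seq_len(attr(folds, "k"))) {
    tr <- which(folds != f); te <- which(folds == f)
    m <- fit_classifier(x[tr, , drop = FALSE], y[tr],
                        classifier = config$classifier,
                        hyper = config$hyper_grid[[1L]])
    pred[te] <- stats::predict(m, x[te, , drop = FALSE], type = "class")
  }
  list(accuracy = mean(pred == y), features = feats)
}
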