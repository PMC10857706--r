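# The per-omics modelling pipeline as a single fitting function:
# preprocessing (outlier removal, missingness filter, imputation) ->
# filter feature selection -> classifier, with every statistic learned on
# the training data only and frozen into the returned object. This is the
# unit that nested cross-validation resamples and that external validation
# transfers.

#' One point of the pipeline configuration grid
#'
#' @param selection A [selection_config()].
#' @param imputation An [imputation_spec()] (proteomic matrices only;
#'   transcriptomic data passes through untouched).
#' @param classifier `"kNN"`, `"LR"`, `"SVM-linear"` or `"SVM-rbf"`.
#' @param hyper_grid Numeric vector of candidate hyperparameters tuned by
#'   inner cross-validation.
#' @param dominance_ratio Outlier-feature dominance ratio (default 10).
#' @return A list of class `pipeline_config` with a deterministic `id`.
#' @export
pipeline_config <- function(selection = selection_config(),
                            imputation = imputation_spec(),
                            classifier = c("LR", "kNN", "SVM-linear", "SVM-rbf"),
                            hyper_grid = 1,
                            dominance_ratio = 10) {
  classifier <- match.arg(classifier)
  if (length(hyper_grid) == 0L) stop("hyper_grid must be non-empty")
  cfg <- list(selection = selection, imputation = imputation,
              classifier = classifier, hyper_grid = hyper_grid,
              dominance_ratio = dominance_ratio)
  cfg$id <- sprintf("%s%d_%s_t%g_%s", selection$method, selection$size,
                    imputation$strategy, imputation$threshold_pct, classifier)
  class(cfg) <- "pipeline_config"
  cfg
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>", x$id, "\n")
  invisible(x)
}

run_selection <- function(fm, labels, selection) {
  scores <- if (selection$method == "DE") de_test(fm, labels)
  else information_gain(fm, labels, bins = selection$ig_bins)
  select_top(scores, selection)
}

#' Fit the full per-omics pipeline
#'
#' Applies preprocessing, runs feature selection, and fits the classifier,
#' all on the supplied (training) data. The returned object freezes the
#' preprocessing statistics (surviving features, imputation medians) and
#' standardization so that [predict.omics_pipeline()] and
#' [external_validation()] never touch held-out information.
#'
#' @param fm A [feature_matrix()] (features x samples).
#' @param labels Class labels, one per sample column.
#' @param config A [pipeline_config()].
#' @param hyper Hyperparameter to use (default: first grid point).
#' @return Object of class `omics_pipeline`, or `NULL` with a warning if
#'   selection retains no features.
#' @export
fit_pipeline <- function(fm, labels, config, hyper = config$hyper_grid[1L]) {
  prep <- preprocess_fit(fm, spec = config$imputation,
                         dominance_ratio = config$dominance_ratio,
                         remove_outliers = omics_tag(fm) == "transcriptomic")
  feats <- run_selection(prep$matrix, labels, config$selection)
  if (length(feats) == 0L) {
    warning("selection shortfall to 0 features for config ", config$id)
    return(NULL)
  }
  x <- t(unclass(prep$matrix)[feats, , drop = FALSE])
  model <- fit_classifier(x, labels, classifier = config$classifier,
                          hyper = hyper)
  structure(list(config = config, prep = prep, features = feats,
                 model = model, omics = omics_tag(fm),
                 n_train = ncol(fm)),
            class = "omics_pipeline")
}

#' @export
print.omics_pipeline <- function(x, ...) {
  cat(sprintf("<omics_pipeline> %s | %s | %d features selected (of %d kept)\n",
              x$omics, x$config$id, length(x$features),
              length(x$prep$features)))
  invisible(x)
}

#' @export
summary.omics_pipeline <- function(object, ...) {
  cat("Omics pipeline fit\n")
  cat("  platform:   ", object$omics, "\n")
  cat("  config:     ", object$config$id, "\n")
  cat("  classifier: ", object$model$classifier,
      " (hyper = ", format(object$model$hyper), ")\n", sep = "")
  cat("  features:   ", length(object$features), " selected; shortfall: ",
      isTRUE(attr(object$features, "shortfall")), "\n", sep = "")
  cat("  removed:    ", length(object$prep$removed_outliers), " outlier, ",
      length(object$prep$removed_missing), " missingness\n", sep = "")
  invisible(object)
}

#' Predict from a fitted pipeline
#'
#' @param object An `omics_pipeline`.
#' @param fm A [feature_matrix()] containing the pipeline's features.
#' @param type `"prob"` or `"class"`.
#' @param ... Unused.
#' @export
predict.omics_pipeline <- function(object, fm, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  fm <- preprocess_apply(object$prep, fm)
  x <- t(unclass(fm)[object$features, , drop = FALSE])
  stats::predict(object$model, x, type = type)
}

#' @export
coef.omics_pipeline <- function(object, ...) coef(object$model)
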