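# Preprocessing ahead of feature selection: dominance-based outlier-feature
# removal, missingness filtering at the imputation threshold, and median /
# zero imputation. The fit/apply split lets training-set statistics be
# frozen and reused on held-out or external data.

#' Imputation specification
#'
#' @param strategy `"none"`, `"median"` (per-feature median of observed
#'   values) or `"zero"`.
#' @param threshold_pct Missingness threshold in percent. A feature is
#'   imputable only if less than `threshold_pct`% of its samples are
#'   missing; at threshold 0 no imputation takes place and every feature
#'   with any missing value is removed. Conventional grid: 0, 5, 10.
#' @return A list of class `imputation_spec`.
#' @export
imputation_spec <- function(strategy = c("none", "median", "zero"),
                            threshold_pct = 0) {
  strategy <- match.arg(strategy)
  stopifnot_scalar_number(threshold_pct, "threshold_pct", 0, 100)
  structure(list(strategy = strategy, threshold_pct = threshold_pct),
            class = "imputation_spec")
}

#' Remove single-sample-dominated outlier features
#'
#' A feature is removed iff its largest observed value exceeds
#' `dominance_ratio` times its second-largest observed value (and the
#' largest value is positive): one sample drives the whole feature. Order
#' of surviving features is preserved.
#'
#' @param matrix A [feature_matrix()] with at least 3 samples.
#' @param dominance_ratio Ratio > 1 (default 10).
#' @return List with `matrix` (filtered) and `removed` (feature ids).
#' @export
remove_outlier_features <- function(matrix, dominance_ratio = 10) {
  if (dominance_ratio <= 1) stop("parameter 'dominance_ratio' must be > 1")
  if (ncol(matrix) < 3L) {
    stop("outlier rule undefined for matrices with fewer than 3 samples")
  }
  drop <- vapply(seq_len(nrow(matrix)), function(i) {
    x <- sort(matrix[i, ][!is.na(matrix[i, ])], decreasing = TRUE)
    length(x) >= 2L && x[1L] > 0 && x[1L] > dominance_ratio * x[2L]
  }, logical(1))
  list(matrix = fm_subset(matrix, features = which(!drop)),
       removed = rownames(matrix)[drop])
}

#' Filter features by missingness fraction
#'
#' Removes features whose missing fraction (in percent) is at or above
#' `threshold_pct`; at threshold 0 every feature with any missing value is
#' removed (the no-imputation case).
#'
#' @param matrix A [feature_matrix()].
#' @param threshold_pct Threshold in percent, >= 0.
#' @return List with `matrix` (filtered) and `removed` (feature ids).
#' @export
filter_by_missingness <- function(matrix, threshold_pct) {
  stopifnot_scalar_number(threshold_pct, "threshold_pct", lower = 0)
  pct <- 100 * rowMeans(is.na(matrix))
  drop <- if (threshold_pct == 0) pct > 0 else pct >= threshold_pct
  list(matrix = fm_subset(matrix, features = which(!drop)),
       removed = rownames(matrix)[drop])
}

#' Impute missing entries
#'
#' Median imputation replaces each missing entry with the median of the
#' feature's observed values; zero imputation replaces them with 0.
#' Observed entries are never altered; the operation is idempotent.
#' Intended to run after [filter_by_missingness()] at the matching
#' threshold.
#'
#' @param matrix A [feature_matrix()].
#' @param spec An [imputation_spec()].
#' @param medians Optional named vector of frozen per-feature medians (from
#'   a training fit) used instead of medians computed on `matrix` itself.
#' @return A complete [feature_matrix()] (strategy `"none"` requires the
#'   input to be complete already).
#' @export
impute <- function(matrix, spec, medians = NULL) {
  if (!inherits(spec, "imputation_spec")) stop("'spec' must be an imputation_spec")
  if (!anyNA(matrix)) return(matrix)
  if (spec$strategy == "none") {
    stop("strategy 'none' cannot handle remaining missing values; ",
         "filter at threshold 0 first")
  }
  v <- unclass(matrix); tag <- omics_tag(matrix); attr(v, "omics_tag") <- NULL
  if (spec$strategy == "zero") {
    v[is.na(v)] <- 0
  } else {
    fill <- if (is.null(medians)) {
      m <- apply(v, 1L, stats::median, na.rm = TRUE)
      if (anyNA(m)) {
        stop("median undefined for feature with all values missing: ",
             rownames(v)[is.na(m)][1L])
      }
      m
    } else {
      m <- medians[rownames(v)]
      if (anyNA(m)) {
        stop("no frozen median for feature: ",
             rownames(v)[is.na(m)][1L])
      }
      m
    }
    idx <- which(is.na(v), arr.ind = TRUE)
    v[idx] <- fill[idx[, 1L]]
  }
  feature_matrix(v, tag)
}

# --- internal fit/apply pair used by the pipeline ------------------------

# Learn preprocessing on a training matrix: outlier removal (transcriptomic
# only by default), missingness filtering + imputation (proteomic). Returns
# the processed training matrix plus frozen statistics.
preprocess_fit <- function(fm, spec = imputation_spec(),
                           dominance_ratio = 10, remove_outliers = TRUE) {
  removed_outliers <- character()
  if (remove_outliers && ncol(fm) >= 3L) {
    out <- remove_outlier_features(fm, dominance_ratio)
    fm <- out$matrix; removed_outliers <- out$removed
  }
  removed_missing <- character()
  medians <- NULL
  if (omics_tag(fm) == "proteomic") {
    flt <- filter_by_missingness(fm, spec$threshold_pct)
    fm <- flt$matrix; removed_missing <- flt$removed
    if (spec$strategy == "median") {
      # frozen even when training happens to be complete, so held-out data
      # is always imputed from training statistics
      medians <- apply(unclass(fm), 1L, stats::median, na.rm = TRUE)
    }
    if (anyNA(fm)) fm <- impute(fm, spec, medians = medians)
  }
  list(matrix = fm, features = rownames(fm), spec = spec,
       medians = medians, removed_outliers = removed_outliers,
       removed_missing = removed_missing)
}

# Apply frozen preprocessing to new data: restrict to the training feature
# set and impute with training medians (or zeros).
preprocess_apply <- function(prep, fm) {
  miss <- setdiff(prep$features, rownames(fm))
  if (length(miss) > 0L) {
    stop("feature id absent from matrix: ", miss[1L])
  }
  fm <- fm_subset(fm, features = prep$features)
  if (anyNA(fm)) fm <- impute(fm, prep$spec, medians = prep$medians)
  fm
}
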