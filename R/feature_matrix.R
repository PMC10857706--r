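#' Construct a feature-by-sample matrix
#'
#' The basic data container of the workflow: a numeric matrix with features
#' as rows and samples as columns, tagged with its omics platform. Missing
#' entries (proteomic dropout) are encoded as `NA`. Transcriptomic matrices
#' must be complete, integer-valued and non-negative.
#'
#' @param values Numeric matrix, features x samples, with unique non-empty
#'   dimnames. `NA` marks a missing entry.
#' @param omics `"transcriptomic"` or `"proteomic"`.
#' @return An object of class `feature_matrix` (a matrix with an
#'   `omics_tag` attribute).
#' @export
feature_matrix <- function(values, omics = c("transcriptomic", "proteomic")) {
  omics <- match.arg(omics)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("'values' must be a numeric matrix")
  }
  fid <- rownames(values)
  sid <- colnames(values)
  if (is.null(fid) && nrow(values) == 0L) rownames(values) <- fid <- character()
  if (is.null(sid) && ncol(values) == 0L) colnames(values) <- sid <- character()
  if (is.null(fid) || is.null(sid) || any(fid == "") || any(sid == "")) {
    stop("feature and sample ids (dimnames) are required")
  }
  if (anyDuplicated(fid)) {
    stop("duplicate feature id: ", fid[duplicated(fid)][1L])
  }
  if (anyDuplicated(sid)) {
    stop("duplicate sample id: ", sid[duplicated(sid)][1L])
  }
  if (omics == "transcriptomic") {
    if (anyNA(values)) {
      stop("transcriptomic matrices must not contain missing values")
    }
    if (any(values < 0) || any(values != round(values))) {
      stop("transcriptomic values must be non-negative integers (counts)")
    }
  }
  structure(values, class = c("feature_matrix", class(values)), omics_tag = omics)
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %s: %d features x %d samples, %d missing\n",
              omics_tag(x), nrow(x), ncol(x), sum(is.na(x))))
  invisible(x)
}

#' Omics platform tag of a feature matrix
#' @param x A `feature_matrix`.
#' @return `"transcriptomic"` or `"proteomic"`.
#' @export
omics_tag <- function(x) attr(x, "omics_tag")

# Subset while keeping class and tag; base `[` would drop them. Trusted
# internal path: no re-validation (subsets of valid matrices stay valid).
fm_subset <- function(x, features = NULL, samples = NULL) {
  tag <- omics_tag(x)
  v <- unclass(x)
  attr(v, "omics_tag") <- NULL
  if (!is.null(features)) v <- v[features, , drop = FALSE]
  if (!is.null(samples))  v <- v[, samples, drop = FALSE]
  if (nrow(v) == 0L && is.null(rownames(v))) rownames(v) <- character()
  if (ncol(v) == 0L && is.null(colnames(v))) colnames(v) <- character()
  structure(v, class = c("feature_matrix", "matrix", "array"),
            omics_tag = tag)
}

#' Validate a sample metadata table
#'
#' Checks the columns `sample_id`, `participant_id`, `class_label`
#' (AH/CT/AC), `tissue` (liver/PBMC) and `omics_tag`
#' (transcriptomic/proteomic), uniqueness of `sample_id`, and returns the
#' table with `class_label` as a factor in canonical order.
#'
#' @param samples A data frame.
#' @return The validated data frame.
#' @export
validate_samples <- function(samples) {
  need <- c("sample_id", "participant_id", "class_label", "tissue", "omics_tag")
  miss <- setdiff(need, names(samples))
  if (length(miss) > 0L) {
    stop("sample table is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(samples$sample_id)) {
    stop("duplicate sample_id: ",
         samples$sample_id[duplicated(samples$sample_id)][1L])
  }
  samples$class_label <- as_ald_factor(samples$class_label)
  bad_t <- setdiff(unique(samples$tissue), c("liver", "PBMC"))
  if (length(bad_t) > 0L) stop("unknown tissue: ", paste(bad_t, collapse = ", "))
  bad_o <- setdiff(unique(samples$omics_tag), c("transcriptomic", "proteomic"))
  if (length(bad_o) > 0L) stop("unknown omics_tag: ", paste(bad_o, collapse = ", "))
  samples
}

# labels for the columns of `fm`, from a sample table
labels_for <- function(fm, samples) {
  idx <- match(colnames(fm), samples$sample_id)
  if (anyNA(idx)) {
    stop("sample id(s) absent from sample table: ",
         paste(colnames(fm)[is.na(idx)], collapse = ", "))
  }
  as_ald_factor(samples$class_label[idx])
}
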