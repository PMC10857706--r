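# Readers/writers for the on-disk formats: feature-matrix TSV (features as
# rows, samples as columns, empty cell / NA / NaN = missing), sample-table
# TSV, gene-protein mapping TSV, GMT term sets, and the YAML run
# configuration. Readers reject malformed input rather than coerce.

NA_TOKENS <- c("", "NA", "NaN")

#' Read a feature-by-sample matrix from TSV
#'
#' The first column holds feature ids, the header row sample ids. For
#' proteomic matrices, empty cells and the tokens `NA`/`NaN` become missing
#' entries; a transcriptomic file containing any such token is rejected.
#'
#' @param path Path to a tab-separated file.
#' @param omics `"transcriptomic"` or `"proteomic"`.
#' @return A [feature_matrix()].
#' @export
read_feature_matrix <- function(path, omics = c("transcriptomic", "proteomic")) {
  omics <- match.arg(omics)
  if (!file.exists(path)) stop("file not found: ", path)
  nf <- utils::count.fields(path, sep = "\t", quote = "", blank.lines.skip = FALSE)
  if (length(unique(nf)) != 1L) {
    stop("format error in ", path, ": ragged rows (",
         length(unique(nf)), " distinct field counts)")
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          na.strings = NA_TOKENS, check.names = FALSE,
                          colClasses = "character", blank.lines.skip = FALSE)
  fid <- df[[1L]]
  if (anyDuplicated(fid)) {
    stop("format error in ", path, ": duplicate feature id '",
         fid[duplicated(fid)][1L], "'")
  }
  body <- df[, -1L, drop = FALSE]
  vals <- suppressWarnings(vapply(body, as.numeric, numeric(nrow(body))))
  if (nrow(body) == 1L) vals <- matrix(vals, nrow = 1L, dimnames = list(NULL, names(body)))
  introduced <- is.na(vals) & !is.na(as.matrix(body))
  if (any(introduced)) {
    stop("format error in ", path, ": non-numeric value '",
         as.matrix(body)[introduced][1L], "'")
  }
  if (omics == "transcriptomic" && anyNA(vals)) {
    stop("format error in ", path,
         ": missing values are not allowed in a transcriptomic matrix")
  }
  rownames(vals) <- fid
  feature_matrix(vals, omics)
}

#' Write a feature matrix to TSV
#'
#' Missing entries are written as empty cells, the convention
#' [read_feature_matrix()] parses back.
#'
#' @param fm A [feature_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(fm, path) {
  df <- data.frame(feature_id = rownames(fm), unclass(fm),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read annotation term sets from a GMT file
#'
#' Standard GMT: one term per line, tab-separated as
#' `term <TAB> description <TAB> member1 <TAB> member2 ...`. Lines with
#' fewer than three fields (i.e. no members) are format errors.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors (term -> member ids).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  out <- vector("list", length(lines))
  nm <- character(length(lines))
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    members <- parts[-(1:2)]
    members <- members[nzchar(members)]
    if (length(parts) < 3L || length(members) == 0L) {
      stop("format error in ", path, " line ", i,
           ": GMT line needs term, description and at least one member")
    }
    nm[[i]] <- parts[[1L]]
    out[[i]] <- unique(members)
  }
  if (anyDuplicated(nm)) {
    stop("format error in ", path, ": duplicate term '",
         nm[duplicated(nm)][1L], "'")
  }
  names(out) <- nm
  out
}

#' Write annotation term sets to a GMT file
#'
#' @param annotations Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional character vector of term descriptions
#'   (defaults to `"na"`).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(annotations, path, descriptions = NULL) {
  if (is.null(names(annotations)) || any(!nzchar(names(annotations)))) {
    stop("annotations must be a named list")
  }
  if (any(lengths(annotations) == 0L)) stop("empty term set cannot be written")
  if (is.null(descriptions)) descriptions <- rep("na", length(annotations))
  lines <- mapply(function(term, desc, members) {
    paste(c(term, desc, members), collapse = "\t")
  }, names(annotations), descriptions, annotations)
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene-protein identifier mapping
#'
#' TSV with columns `protein_id`, `gene_id`, `relation`; `relation` must be
#' `direct` (protein mapped to its coding gene) or `familial` (same-family
#' paralog, e.g. the GSTA1 protein matched to the GSTA2 gene). A zero-byte
#' or header-only file yields an empty map.
#'
#' @param path Path to the mapping TSV.
#' @return Data frame with the three columns.
#' @export
read_mapping <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  empty <- data.frame(protein_id = character(), gene_id = character(),
                      relation = character(), stringsAsFactors = FALSE)
  if (file.size(path) == 0L) return(empty)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          colClasses = "character", check.names = FALSE)
  need <- c("protein_id", "gene_id", "relation")
  if (!all(need %in% names(df))) {
    stop("format error in ", path, ": expected columns ",
         paste(need, collapse = ", "))
  }
  if (nrow(df) == 0L) return(empty)
  bad <- setdiff(unique(df$relation), c("direct", "familial"))
  if (length(bad) > 0L) {
    stop("format error in ", path, ": unknown relation token '", bad[1L], "'")
  }
  df[, need]
}

#' Write a gene-protein mapping TSV
#' @param map Data frame with columns `protein_id`, `gene_id`, `relation`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mapping <- function(map, path) {
  utils::write.table(map[, c("protein_id", "gene_id", "relation")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a sample metadata table
#'
#' @param path Path to a TSV with columns `sample_id`, `participant_id`,
#'   `class_label`, `tissue`, `omics_tag`.
#' @return Validated data frame (see [validate_samples()]).
#' @export
read_sample_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          colClasses = "character", check.names = FALSE)
  validate_samples(df)
}

#' @rdname read_sample_table
#' @param samples Sample table to write.
#' @export
write_sample_table <- function(samples, path) {
  out <- samples
  out$class_label <- as.character(out$class_label)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a run configuration from YAML
#'
#' The configuration carries the pipeline grids (feature sizes per omics,
#' imputation strategies and thresholds, classifiers and their
#' hyperparameter grids), fold counts and seeds. Missing entries are filled
#' from [default_run_config()].
#'
#' @param path Path to a YAML file (or `NULL` for pure defaults).
#' @return A named list.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    cfg[names(user)] <- user
  }
  if (length(cfg$feature_sizes$transcriptomic) == 0L ||
      length(cfg$feature_sizes$proteomic) == 0L) {
    stop("feature size grids must be non-empty")
  }
  if (!is.numeric(cfg$seed) || cfg$seed != round(cfg$seed)) {
    stop("seed must be an integer")
  }
  cfg
}

#' Default run configuration
#'
#' Grids follow the study design: transcriptomic feature sizes 10-500,
#' proteomic sizes 15-200 (smaller proteomic cohorts warrant the lower
#' ceiling), imputation none/median/zero at thresholds 0/5/10%, classifiers
#' kNN/LR/SVM for single-omics stages and LR / linear-SVM for integration.
#'
#' @return A named list.
#' @export
default_run_config <- function() {
  list(
    feature_sizes = list(
      transcriptomic = c(10, 25, 50, 100, 150, 200, 250, 300, 350, 400, 450, 500),
      proteomic = c(15, 25, 35, 50, 60, 70, 80, 90, 100, 150, 200)
    ),
    imputation = list(strategies = c("median", "zero"),
                      thresholds = c(0, 5, 10)),
    classifiers = c("kNN", "LR", "SVM-linear", "SVM-rbf"),
    hyper_grids = list(kNN = c(3, 5, 7),
                       LR = c(0.01, 0.1, 1, 10),
                       `SVM-linear` = c(0.1, 1, 10),
                       `SVM-rbf` = c(0.1, 1, 10)),
    q_threshold = 0.05,
    ig_bins = 3,
    k_outer = 5,
    k_inner = 3,
    min_unmatched_per_class = 7,
    seed = 1
  )
}
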