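# Matched/unmatched sample partitioning. A sample is "matched" when its
# participant contributed a sample to the other omics platform in the same
# tissue. Because some per-class unmatched pools are too small for
# cross-validated training, whole matched participants can be moved into
# the unmatched pool ("rebalancing"), producing the matched-balanced /
# unmatched-balanced split used by the integration stages.

#' Split samples into matched and unmatched subsets
#'
#' @param samples A validated sample table covering both omics platforms
#'   (see [validate_samples()]).
#' @param matches Optional match map (ignored; matching is derived from the
#'   table itself: participant present in both omics of the same tissue).
#' @return An object of class `omics_partition`: the sample table with a
#'   `subset` column (`matched`/`unmatched`) and, after [rebalance()], a
#'   `subset_balanced` column.
#' @export
split_by_matching <- function(samples, matches = NULL) {
  samples <- validate_samples(samples)
  key <- paste(samples$participant_id, samples$tissue, samples$omics_tag)
  dup <- duplicated(key)
  if (any(dup)) {
    stop("data error: participant ", samples$participant_id[dup][1L],
         " has more than one ", samples$omics_tag[dup][1L],
         " sample in tissue ", samples$tissue[dup][1L])
  }
  other <- ifelse(samples$omics_tag == "transcriptomic",
                  "proteomic", "transcriptomic")
  other_key <- paste(samples$participant_id, samples$tissue, other)
  samples$subset <- ifelse(other_key %in% key, "matched", "unmatched")
  structure(list(samples = samples), class = "omics_partition")
}

#' @export
print.omics_partition <- function(x, ...) {
  cat("<omics_partition>\n")
  print(partition_counts(x))
  invisible(x)
}

#' Per-class subset counts of a partition
#'
#' @param partition An `omics_partition`.
#' @return Data frame with one row per (omics, class) and columns `full`,
#'   `matched`, `unmatched`, plus `matched_balanced`/`unmatched_balanced`
#'   after [rebalance()].
#' @export
partition_counts <- function(partition) {
  s <- partition$samples
  out <- expand.grid(omics_tag = unique(s$omics_tag),
                     class_label = ALD_CLASSES,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cnt <- function(sub, col = "subset") {
    vapply(seq_len(nrow(out)), function(i) {
      sum(s$omics_tag == out$omics_tag[i] &
            s$class_label == out$class_label[i] &
            (if (is.null(sub)) TRUE else s[[col]] == sub))
    }, integer(1))
  }
  out$full <- cnt(NULL)
  out$matched <- cnt("matched")
  out$unmatched <- cnt("unmatched")
  if (!is.null(s$subset_balanced)) {
    out$matched_balanced <- cnt("matched", "subset_balanced")
    out$unmatched_balanced <- cnt("unmatched", "subset_balanced")
  }
  out
}

#' Rebalance a partition by moving matched participants
#'
#' Tops up each class's unmatched pool to `min_unmatched_per_class` samples
#' per omics by moving whole matched participants (both of their samples
#' move together, keeping the matched pool usable for integration). Movers
#' are drawn by seeded sampling within each class, so the result is
#' deterministic for a fixed seed. Conservation always holds:
#' full = matched_balanced + unmatched_balanced per class and omics.
#'
#' @param partition An `omics_partition` from [split_by_matching()].
#' @param min_unmatched_per_class Target minimum unmatched pool size per
#'   class per omics (default 7).
#' @param seed Integer seed.
#' @return List with elements `partition` (with `subset_balanced`) and
#'   `ledger` (data frame of moved participants per class).
#' @export
rebalance <- function(partition, min_unmatched_per_class = 7, seed = 1) {
  if (min_unmatched_per_class < 0) {
    stop("parameter 'min_unmatched_per_class' must be >= 0")
  }
  s <- partition$samples
  cls_tot <- table(factor(s$class_label, ALD_CLASSES))
  if (any(cls_tot < 1)) {
    stop("data error: class ", names(cls_tot)[cls_tot < 1][1L], " has no samples")
  }
  s$subset_balanced <- s$subset
  moved <- list()
  with_seed(seed, {
    for (cl in ALD_CLASSES) {
      in_cl <- s$class_label == cl
      # matched participants move as a unit: one per omics each
      cand <- unique(s$participant_id[in_cl & s$subset == "matched"])
      # deficit per omics; moving one matched participant adds one sample
      # to each omics' unmatched pool
      deficits <- vapply(unique(s$omics_tag), function(om) {
        have <- sum(in_cl & s$omics_tag == om & s$subset == "unmatched")
        max(0L, as.integer(min_unmatched_per_class) - have)
      }, integer(1))
      k <- min(length(cand), max(deficits))
      if (k > 0L) {
        movers <- sort(cand)[sample.int(length(cand), k)]
        s$subset_balanced[s$participant_id %in% movers & in_cl] <- "unmatched"
        moved[[cl]] <- movers
      }
    }
  })
  partition$samples <- s
  ledger <- data.frame(
    class_label = rep(names(moved), lengths(moved)),
    participant_id = unlist(moved, use.names = FALSE),
    stringsAsFactors = FALSE)
  list(partition = partition, ledger = ledger)
}

#' Verify partition count conservation
#'
#' Checks, per class, that the full count equals the matched-balanced plus
#' unmatched-balanced counts.
#'
#' @param full,matched_balanced,unmatched_balanced Named (by class) or
#'   equal-length integer vectors of per-class counts.
#' @return Data frame with columns `class_label`, `full`,
#'   `matched_balanced`, `unmatched_balanced`, `pass`, `deficit`
#'   (full - mb - ub).
#' @export
verify_conservation <- function(full, matched_balanced, unmatched_balanced) {
  if (length(full) != length(matched_balanced) ||
      length(full) != length(unmatched_balanced)) {
    stop("count vectors must have equal length")
  }
  cl <- names(full)
  if (is.null(cl)) cl <- paste0("class", seq_along(full))
  deficit <- as.integer(full) - as.integer(matched_balanced) -
    as.integer(unmatched_balanced)
  data.frame(class_label = cl,
             full = as.integer(full),
             matched_balanced = as.integer(matched_balanced),
             unmatched_balanced = as.integer(unmatched_balanced),
             pass = deficit == 0L,
             deficit = deficit,
             stringsAsFactors = FALSE)
}

#' Sample-matching census of the motivating liver-disease study
#'
#' Reads the per-class matched/unmatched sample counts of the
#' alcohol-associated liver disease cohort (liver tissue and PBMC, both
#' platforms) shipped with the package, for use with
#' [verify_conservation()].
#'
#' @return Data frame with columns `tissue`, `omics_tag`, `class_label`,
#'   `full`, `matched`, `unmatched`, `matched_balanced`,
#'   `unmatched_balanced`.
#' @export
ald_matching_counts <- function() {
  path <- system.file("extdata", "ald_matching_counts.tsv",
                      package = "omicstack", mustWork = TRUE)
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}
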