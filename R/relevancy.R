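# Local in-silico relevancy scoring of candidate panels: one-sided
# hypergeometric over-representation against user-supplied term sets with
# BH correction, plus the lexicographic best-candidate rule (accuracy,
# then least imputation for proteomics, then relevancy, then panel size).

#' Hypergeometric over-representation test
#'
#' For each term, `p = P[X >= overlap]` with
#' `X ~ Hypergeometric(universe, term ∩ universe, query)`; q-values by
#' [bh_adjust()] across terms. Terms are intersected with the universe
#' first; the query must be a subset of the universe.
#'
#' @param query Character vector of feature ids (non-empty).
#' @param annotations Named list of character vectors.
#' @param universe Character vector of all testable feature ids.
#' @return Data frame with columns `term`, `overlap`, `term_size`,
#'   `query_size`, `universe_size`, `p_value`, `q_value`.
#' @export
hypergeometric_enrichment <- function(query, annotations, universe) {
  query <- unique(query); universe <- unique(universe)
  if (length(query) == 0L) stop("empty query set")
  if (length(universe) == 0L) stop("empty universe")
  extra <- setdiff(query, universe)
  if (length(extra) > 0L) {
    stop("query id(s) outside the universe: ", extra[1L])
  }
  U <- length(universe); q <- length(query)
  rows <- lapply(names(annotations), function(tm) {
    term <- intersect(annotations[[tm]], universe)
    ov <- length(intersect(query, term))
    p <- stats::phyper(ov - 1L, length(term), U - length(term), q,
                       lower.tail = FALSE)
    data.frame(term = tm, overlap = ov, term_size = length(term),
               query_size = q, universe_size = U, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- bh_adjust(out$p_value)
  out[order(out$p_value, out$term), ]
}

#' Relevancy score of an enrichment result
#'
#' Counts terms with `q <= q_threshold` and records the best
#' `-log10(q)`. This makes the informal "biological relevancy" criterion
#' explicit and configurable.
#'
#' @param results Output of [hypergeometric_enrichment()] for one query.
#' @param q_threshold Significance gate (default 0.05).
#' @return List with `n_significant_terms` and `best_neg_log10_q`.
#' @export
score_relevancy <- function(results, q_threshold = 0.05) {
  sig <- results$q_value <= q_threshold
  list(n_significant_terms = sum(sig),
       best_neg_log10_q = if (nrow(results) > 0L)
         max(-log10(pmax(results$q_value, 1e-300))) else 0)
}

# imputation amount for the "least imputation preferred" ordering:
# none < any strategy at threshold 5 < threshold 10; zero/median tie at
# equal threshold.
imputation_amount <- function(spec) {
  if (spec$strategy == "none" || spec$threshold_pct == 0) 0 else spec$threshold_pct
}

#' Select the best candidate panel
#'
#' Lexicographic rule: (1) outer accuracy, descending; (2) proteomic data
#' only: imputation amount, ascending (least imputation preferred);
#' (3) relevancy, descending; (4) panel size, ascending; (5) config id.
#' The rule is a total order, so the winner is unique.
#'
#' @param candidates List of `candidate_result` objects (e.g. an
#'   `ncv_result`), each optionally carrying a `relevancy` element as
#'   produced by [score_relevancy()] (missing relevancy counts as 0).
#' @param omics_tag `"transcriptomic"` or `"proteomic"`; the imputation
#'   tie-break applies to proteomic data only.
#' @return The winning `candidate_result`, with attribute `audit` (the
#'   ranking table).
#' @export
select_best_candidate <- function(candidates,
                                  omics_tag = c("transcriptomic", "proteomic")) {
  omics_tag <- match.arg(omics_tag)
  candidates <- unname(as.list(candidates))
  if (length(candidates) == 0L) stop("empty candidate list")
  key <- data.frame(
    idx = seq_along(candidates),
    accuracy = vapply(candidates, function(c) c$outer_accuracy, numeric(1)),
    imputation = vapply(candidates, function(c)
      imputation_amount(c$config$imputation), numeric(1)),
    relevancy = vapply(candidates, function(c)
      if (is.null(c$relevancy)) 0 else c$relevancy$n_significant_terms,
      numeric(1)),
    size = vapply(candidates, function(c)
      length(c$final_features %||% c$consensus_features), integer(1)),
    id = vapply(candidates, function(c) c$config$id, character(1)),
    stringsAsFactors = FALSE)
  ord <- if (omics_tag == "proteomic") {
    order(-key$accuracy, key$imputation, -key$relevancy, key$size, key$id)
  } else {
    order(-key$accuracy, -key$relevancy, key$size, key$id)
  }
  winner <- candidates[[ord[1L]]]
  attr(winner, "audit") <- key[ord, ]
  winner
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L) b else a

#' Attach relevancy scores to NCV candidates
#'
#' Runs [hypergeometric_enrichment()] on each candidate's panel (its
#' final feature list) and stores the [score_relevancy()] summary.
#'
#' @param results An `ncv_result`.
#' @param annotations Named list of term sets.
#' @param universe All testable feature ids.
#' @return The `ncv_result` with a `relevancy` element per candidate.
#' @export
add_relevancy <- function(results, annotations, universe) {
  for (i in seq_along(results)) {
    panel <- results[[i]]$final_features %||% results[[i]]$consensus_features
    panel <- intersect(panel, universe)
    results[[i]]$relevancy <- if (length(panel) == 0L) {
      list(n_significant_terms = 0L, best_neg_log10_q = 0)
    } else {
      score_relevancy(hypergeometric_enrichment(panel, annotations, universe))
    }
  }
  results
}
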