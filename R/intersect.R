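# Gene-protein panel intersection: which proteins in the winning protein
# panel match (directly, or through a gene family) genes in the winning
# gene panel, and how many matches random panels of the same sizes drawn
# from the significant sets would share in expectation.

#' Match a gene panel against a protein panel
#'
#' A pair `(protein, gene)` is reported iff the protein is in the protein
#' panel, the gene in the gene panel, and the pair (with its relation,
#' `direct` or `familial`) is in the mapping.
#'
#' @param gene_panel,protein_panel Character vectors of ids.
#' @param gene_protein_map Data frame with columns `protein_id`,
#'   `gene_id`, `relation` (see [read_mapping()]).
#' @return List of class `match_report` with `pairs` (the matching rows),
#'   `n_direct`, `n_familial`, `observed_shared`.
#' @export
match_panels <- function(gene_panel, protein_panel, gene_protein_map) {
  m <- gene_protein_map
  hit <- m$protein_id %in% protein_panel & m$gene_id %in% gene_panel
  pairs <- m[hit, , drop = FALSE]
  structure(list(pairs = pairs,
                 n_direct = sum(pairs$relation == "direct"),
                 n_familial = sum(pairs$relation == "familial"),
                 observed_shared = nrow(pairs)),
            class = "match_report")
}

#' @export
print.match_report <- function(x, ...) {
  cat(sprintf("<match_report> %d shared pair(s): %d direct, %d familial\n",
              x$observed_shared, x$n_direct, x$n_familial))
  if (x$observed_shared > 0) {
    apply(x$pairs, 1L, function(r)
      cat(sprintf("  %s (protein) ~ %s (gene), %s\n",
                  r[["protein_id"]], r[["gene_id"]], r[["relation"]])))
  }
  invisible(x)
}

#' Expected shared matches under random panel selection
#'
#' If `k_genes` of `n_sig_genes` significant genes and `k_proteins` of
#' `n_sig_proteins` significant proteins were drawn uniformly without
#' replacement, each of the `matching_pairs` gene-protein pairs within the
#' significant sets appears in both panels with probability
#' `(k_genes / n_sig_genes) * (k_proteins / n_sig_proteins)`; by linearity
#' the expected shared count is the sum over pairs. Exact, no simulation.
#'
#' @param k_genes,k_proteins Panel sizes.
#' @param n_sig_genes,n_sig_proteins Sizes of the significant sets.
#' @param matching_pairs Number of mapped pairs within the significant
#'   sets.
#' @return Expected shared count (non-negative real).
#' @export
expected_shared <- function(k_genes, n_sig_genes, k_proteins,
                            n_sig_proteins, matching_pairs) {
  if (n_sig_genes <= 0 || n_sig_proteins <= 0) {
    stop("significant sets must be non-empty")
  }
  if (k_genes > n_sig_genes || k_proteins > n_sig_proteins) {
    stop("panel size exceeds its significant set")
  }
  if (matching_pairs < 0) stop("matching_pairs must be >= 0")
  matching_pairs * (k_genes / n_sig_genes) * (k_proteins / n_sig_proteins)
}

#' Monte-Carlo estimate of the shared-match count
#'
#' Simulation oracle for [expected_shared()]: draws uniform panels without
#' replacement and counts mapped pairs present in both.
#'
#' @param k_genes,n_sig_genes,k_proteins,n_sig_proteins As in
#'   [expected_shared()].
#' @param pairs Two-column integer matrix of (gene index, protein index)
#'   pairs within `1..n_sig_genes` x `1..n_sig_proteins`.
#' @param n_draws Number of simulated selections (>= 1).
#' @param seed Integer seed.
#' @return List with `mean` and `se`.
#' @export
monte_carlo_shared <- function(k_genes, n_sig_genes, k_proteins,
                               n_sig_proteins, pairs, n_draws = 1e4,
                               seed = 1) {
  if (n_draws < 1) stop("n_draws must be >= 1")
  pairs <- matrix(as.integer(pairs), ncol = 2L)
  with_seed(seed, {
    counts <- vapply(seq_len(n_draws), function(i) {
      g <- sample.int(n_sig_genes, k_genes)
      p <- sample.int(n_sig_proteins, k_proteins)
      if (nrow(pairs) == 0L) 0L else
        sum(pairs[, 1L] %in% g & pairs[, 2L] %in% p)
    }, integer(1))
    list(mean = mean(counts), se = stats::sd(counts) / sqrt(n_draws))
  })
}
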