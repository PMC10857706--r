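# Synthetic multi-omics cohort generator. Emulates the statistical
# structure the workflow assumes: three phenotype classes, partially
# matched participants across a transcriptomic and a proteomic platform,
# negative-binomial counts with planted class effects, Gaussian
# log2-intensity proteins with planted effects plus MCAR and
# intensity-dependent (MNAR) missingness, a gene-protein match map, and
# annotation term sets enriched for the planted features.

#' Parameters of a synthetic multi-omics cohort
#'
#' @param n_per_class Samples per class per omics.
#' @param frac_matched Fraction of each class's participants carrying both
#'   omics; `frac_matched * n_per_class` must round cleanly.
#' @param n_genes,n_proteins Feature counts per platform.
#' @param n_de_genes,n_de_proteins Planted discriminative features per
#'   platform; each planted feature is shifted in one designated class.
#' @param effect_log2fc Planted mean shift, log2 scale, in the affected class.
#' @param nb_dispersion Negative-binomial dispersion of the counts
#'   (`Var = mu + dispersion * mu^2`).
#' @param base_mean Baseline count scale; protein baselines sit at
#'   `log2(base_mean) + 14` on the log2-intensity scale.
#' @param prot_sd Proteomic log2-intensity noise SD.
#' @param mcar_rate Completely-at-random missingness fraction in `[0, 1)`.
#' @param mnar_strength Slope (per log2-intensity unit) of the
#'   intensity-dependent dropout; 0 disables MNAR.
#' @param n_matched_pairs Gene-protein pairs linked in the identifier map
#'   among the planted features.
#' @param n_terms,term_size Annotation structure for the local enrichment
#'   universe.
#' @param tissue Tissue label stamped on every sample.
#' @param seed Integer seed; fixed seed gives a bit-identical bundle.
#' @return A list of class `cohort_params`.
#' @export
cohort_params <- function(n_per_class = 20, frac_matched = 0.6,
                          n_genes = 2000, n_proteins = 500,
                          n_de_genes = 100, n_de_proteins = 50,
                          effect_log2fc = 2, nb_dispersion = 0.3,
                          base_mean = 100, prot_sd = 1,
                          mcar_rate = 0.05, mnar_strength = 0.5,
                          n_matched_pairs = 20, n_terms = 50, term_size = 25,
                          tissue = "liver", seed = 1) {
  p <- list(n_per_class = n_per_class, frac_matched = frac_matched,
            n_genes = n_genes, n_proteins = n_proteins,
            n_de_genes = n_de_genes, n_de_proteins = n_de_proteins,
            effect_log2fc = effect_log2fc, nb_dispersion = nb_dispersion,
            base_mean = base_mean, prot_sd = prot_sd,
            mcar_rate = mcar_rate, mnar_strength = mnar_strength,
            n_matched_pairs = n_matched_pairs, n_terms = n_terms,
            term_size = term_size, tissue = tissue, seed = seed)
  stopifnot_scalar_number(p$n_per_class, "n_per_class", lower = 1)
  stopifnot_scalar_number(p$frac_matched, "frac_matched", 0, 1)
  stopifnot_scalar_number(p$n_genes, "n_genes", lower = 1)
  stopifnot_scalar_number(p$n_proteins, "n_proteins", lower = 1)
  stopifnot_scalar_number(p$n_de_genes, "n_de_genes", 0, p$n_genes)
  stopifnot_scalar_number(p$n_de_proteins, "n_de_proteins", 0, p$n_proteins)
  stopifnot_scalar_number(p$nb_dispersion, "nb_dispersion", lower = 0)
  stopifnot_scalar_number(p$base_mean, "base_mean", lower = 1)
  stopifnot_scalar_number(p$prot_sd, "prot_sd", lower = 0)
  stopifnot_scalar_number(p$mcar_rate, "mcar_rate", 0, 1 - 1e-12)
  stopifnot_scalar_number(p$mnar_strength, "mnar_strength", lower = 0)
  stopifnot_scalar_number(p$n_matched_pairs, "n_matched_pairs",
                          0, min(p$n_de_genes, p$n_de_proteins))
  stopifnot_scalar_number(p$n_terms, "n_terms", lower = 1)
  stopifnot_scalar_number(p$term_size, "term_size", lower = 1)
  stopifnot_scalar_number(p$seed, "seed")
  m <- p$frac_matched * p$n_per_class
  if (abs(m - round(m)) > 1e-8) {
    stop("parameter 'frac_matched': frac_matched * n_per_class (", m,
         ") must round to an integer")
  }
  class(p) <- "cohort_params"
  p
}

#' Generate a synthetic multi-omics cohort
#'
#' Counts are negative-binomial around feature-specific baselines; protein
#' log2 intensities are Gaussian. Each planted feature is assigned one
#' affected class (cycling AH, CT, AC) whose mean is shifted by
#' `effect_log2fc` on the log2 scale; non-planted features are exchangeable
#' across classes. Proteomic missingness is injected afterwards via
#' [inject_missingness()].
#'
#' @param params A [cohort_params()] object.
#' @return A list of class `cohort_bundle` with elements `rna`, `prot`
#'   (both [feature_matrix()]), `samples`, `matches`, `gene_protein_map`,
#'   `annotations`, `truth` and `params`.
#' @export
generate_cohort <- function(params) {
  if (!inherits(params, "cohort_params")) params <- do.call(cohort_params, params)
  p <- params
  with_seed(p$seed, {
    classes <- ALD_CLASSES
    n_matched <- round(p$frac_matched * p$n_per_class)
    n_unm <- p$n_per_class - n_matched

    samp <- list(); matches <- list(); pid <- 0L
    for (cl in classes) {
      for (i in seq_len(n_matched)) {
        pid <- pid + 1L
        part <- sprintf("PART%04d", pid)
        rna_id <- sprintf("R_%s", part); prot_id <- sprintf("P_%s", part)
        samp[[length(samp) + 1L]] <- data.frame(
          sample_id = c(rna_id, prot_id), participant_id = part,
          class_label = cl, tissue = p$tissue,
          omics_tag = c("transcriptomic", "proteomic"),
          stringsAsFactors = FALSE)
        matches[[length(matches) + 1L]] <- data.frame(
          participant_id = part, rna_sample = rna_id, prot_sample = prot_id,
          tissue = p$tissue, stringsAsFactors = FALSE)
      }
      for (om in c("transcriptomic", "proteomic")) {
        for (i in seq_len(n_unm)) {
          pid <- pid + 1L
          part <- sprintf("PART%04d", pid)
          sid <- sprintf("%s_%s", if (om == "transcriptomic") "R" else "P", part)
          samp[[length(samp) + 1L]] <- data.frame(
            sample_id = sid, participant_id = part, class_label = cl,
            tissue = p$tissue, omics_tag = om, stringsAsFactors = FALSE)
        }
      }
    }
    samples <- validate_samples(do.call(rbind, samp))
    matches <- if (length(matches)) do.call(rbind, matches) else
      data.frame(participant_id = character(), rna_sample = character(),
                 prot_sample = character(), tissue = character())

    gene_ids <- sprintf("GENE%05d", seq_len(p$n_genes))
    prot_ids <- sprintf("PROT%05d", seq_len(p$n_proteins))
    de_genes <- sort(sample(gene_ids, p$n_de_genes))
    de_prots <- sort(sample(prot_ids, p$n_de_proteins))

    rna_samples <- samples[samples$omics_tag == "transcriptomic", ]
    prot_samples <- samples[samples$omics_tag == "proteomic", ]
    y_rna <- as.character(rna_samples$class_label)
    y_prot <- as.character(prot_samples$class_label)

    # affected class cycles over planted features so the signal is 3-way
    affected_g <- classes[(seq_len(p$n_de_genes) - 1L) %% 3L + 1L]
    affected_p <- classes[(seq_len(p$n_de_proteins) - 1L) %% 3L + 1L]

    # counts: per-gene baseline spread around base_mean (log2-normal, sd 1)
    base_g <- p$base_mean * 2^stats::rnorm(p$n_genes, 0, 1)
    mu <- matrix(base_g, p$n_genes, length(y_rna))
    for (j in seq_len(p$n_de_genes)) {
      gi <- match(de_genes[j], gene_ids)
      mu[gi, y_rna == affected_g[j]] <- base_g[gi] * 2^p$effect_log2fc
    }
    size <- if (p$nb_dispersion > 0) 1 / p$nb_dispersion else Inf
    counts <- matrix(
      if (is.finite(size)) stats::rnbinom(length(mu), mu = mu, size = size)
      else stats::rpois(length(mu), lambda = mu),
      nrow = p$n_genes, dimnames = list(gene_ids, rna_samples$sample_id))
    rna <- feature_matrix(counts, "transcriptomic")

    # proteins: Gaussian log2 intensities around per-protein baselines
    base_p <- 14 + log2(p$base_mean) + stats::rnorm(p$n_proteins, 0, 2)
    mup <- matrix(base_p, p$n_proteins, length(y_prot))
    for (j in seq_len(p$n_de_proteins)) {
      pi <- match(de_prots[j], prot_ids)
      mup[pi, y_prot == affected_p[j]] <- base_p[pi] + p$effect_log2fc
    }
    intens <- mup + stats::rnorm(length(mup), 0, p$prot_sd)
    intens <- pmax(intens, 0.01)   # log2 intensities are positive by convention
    dimnames(intens) <- list(prot_ids, prot_samples$sample_id)
    prot <- feature_matrix(intens, "proteomic")
    prot <- inject_missingness(prot, p$mcar_rate, p$mnar_strength,
                               seed = child_seed(p$seed, 11L))

    # gene-protein map over planted features; every 5th pair familial,
    # simulated as a shared family-root identifier pattern in the relation
    map <- data.frame(protein_id = character(), gene_id = character(),
                      relation = character(), stringsAsFactors = FALSE)
    if (p$n_matched_pairs > 0) {
      idx <- seq_len(p$n_matched_pairs)
      map <- data.frame(protein_id = de_prots[idx], gene_id = de_genes[idx],
                        relation = ifelse(idx %% 5L == 0L, "familial", "direct"),
                        stringsAsFactors = FALSE)
    }

    truth <- list(genes = de_genes, proteins = de_prots)
    annotations <- build_annotation_sets(
      truth_features = c(de_genes, de_prots),
      all_features = c(gene_ids, prot_ids),
      n_terms = p$n_terms, term_size = p$term_size,
      seed = child_seed(p$seed, 23L))

    structure(list(rna = rna, prot = prot, samples = samples,
                   matches = matches, gene_protein_map = map,
                   annotations = annotations, truth = truth, params = p),
              class = "cohort_bundle")
  })
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat(sprintf(paste0("<cohort_bundle> %d genes x %d RNA samples, ",
                     "%d proteins x %d proteomic samples, %d matched participants\n"),
              nrow(x$rna), ncol(x$rna), nrow(x$prot), ncol(x$prot),
              nrow(x$matches)))
  invisible(x)
}

#' Inject MCAR and MNAR missingness into a complete matrix
#'
#' MCAR entries are dropped uniformly at rate `mcar_rate`. MNAR dropout is
#' logistic in the observed intensity, `plogis(mnar_strength * (q10 - x))`
#' with the intercept pinned at the 10th percentile of all intensities, so
#' low-abundance values drop out preferentially; `mnar_strength = 0`
#' disables it exactly.
#'
#' @param matrix A complete [feature_matrix()].
#' @param mcar_rate Fraction in `[0, 1)`.
#' @param mnar_strength Non-negative slope.
#' @param seed Integer seed.
#' @return The matrix with missing entries set to `NA`.
#' @export
inject_missingness <- function(matrix, mcar_rate, mnar_strength, seed = 1) {
  if (anyNA(matrix)) stop("input matrix already contains missing entries")
  stopifnot_scalar_number(mcar_rate, "mcar_rate", 0, 1 - 1e-12)
  stopifnot_scalar_number(mnar_strength, "mnar_strength", lower = 0)
  if (mcar_rate == 0 && mnar_strength == 0) return(matrix)
  tag <- omics_tag(matrix)
  v <- unclass(matrix); attr(v, "omics_tag") <- NULL
  with_seed(seed, {
    drop <- stats::runif(length(v)) < mcar_rate
    if (mnar_strength > 0) {
      q10 <- stats::quantile(v, 0.10, names = FALSE)
      p_mnar <- stats::plogis(mnar_strength * (q10 - v))
      drop <- drop | (stats::runif(length(v)) < p_mnar)
    }
    v[drop] <- NA_real_
  })
  feature_matrix(v, tag)
}

#' Build synthetic annotation term sets
#'
#' One designated `signal` term over-samples the planted features (80% of
#' its members, or all planted features if fewer); the remaining terms are
#' uniform draws from the feature universe. Serves as a local stand-in for
#' a curated enrichment universe.
#'
#' @param truth_features Planted feature ids.
#' @param all_features Full feature universe.
#' @param n_terms Number of terms.
#' @param term_size Members per term; must be positive and at most
#'   `length(all_features)`.
#' @param seed Integer seed.
#' @return Named list of character vectors.
#' @export
build_annotation_sets <- function(truth_features, all_features,
                                  n_terms, term_size, seed = 1) {
  if (term_size < 1) stop("parameter 'term_size' must be >= 1")
  if (term_size > length(all_features)) {
    stop("parameter 'term_size' exceeds the number of features")
  }
  with_seed(seed, {
    out <- vector("list", n_terms)
    n_sig <- min(length(truth_features), max(1L, round(0.8 * term_size)))
    sig <- if (n_sig > 0L) sample(truth_features, n_sig) else character()
    filler <- sample(setdiff(all_features, sig),
                     max(0L, term_size - length(sig)))
    out[[1L]] <- sort(unique(c(sig, filler)))
    for (i in seq_len(n_terms - 1L)) {
      out[[i + 1L]] <- sort(sample(all_features, term_size))
    }
    names(out) <- c("signal_term", sprintf("TERM%04d", seq_len(n_terms - 1L)))
    out
  })
}

#' Write a cohort bundle to a directory
#'
#' Emits `rna.tsv` and `prot.tsv` (feature-matrix TSV, empty cell =
#' missing), `samples.tsv`, `gene_protein_map.tsv`, `annotations.gmt` and a
#' `truth.json` sidecar carrying the planted feature ids and the generating
#' parameters.
#'
#' @param bundle A `cohort_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_feature_matrix(bundle$rna, file.path(dir, "rna.tsv"))
  write_feature_matrix(bundle$prot, file.path(dir, "prot.tsv"))
  write_sample_table(bundle$samples, file.path(dir, "samples.tsv"))
  write_mapping(bundle$gene_protein_map, file.path(dir, "gene_protein_map.tsv"))
  write_gmt(bundle$annotations, file.path(dir, "annotations.gmt"))
  jsonlite::write_json(
    list(truth = bundle$truth, params = unclass(bundle$params)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Simulate complementary per-omics class probabilities
#'
#' Constructs the meta-feature scenario in which the two platforms carry
#' complementary information: omics 1 discriminates AH from the rest but is
#' uninformative between CT and AC; omics 2 discriminates CT from AC but is
#' uninformative about AH. Used to demonstrate the gain from late-fusion
#' stacking.
#'
#' @param n_per_class Participants per class.
#' @param strength Logit separation of the informative contrast.
#' @param noise_sd SD of logit noise.
#' @param seed Integer seed.
#' @return List with `meta` (n x 6 probability matrix, two 3-column blocks
#'   in class order AH, CT, AC) and `labels` (factor).
#' @export
simulate_complementary_probs <- function(n_per_class = 20, strength = 2.5,
                                         noise_sd = 1, seed = 1) {
  with_seed(seed, {
    y <- as_ald_factor(rep(ALD_CLASSES, each = n_per_class))
    n <- length(y)
    softmax <- function(z) {
      e <- exp(z - apply(z, 1L, max))
      e / rowSums(e)
    }
    # omics 1: AH vs rest only
    z1 <- matrix(stats::rnorm(n * 3L, 0, noise_sd), n, 3L)
    z1[, 1L] <- z1[, 1L] + strength * (2 * (y == "AH") - 1)
    # omics 2: CT vs AC only, silent on AH
    z2 <- matrix(stats::rnorm(n * 3L, 0, noise_sd), n, 3L)
    z2[, 2L] <- z2[, 2L] + strength * (y == "CT") - strength * (y == "AC")
    z2[, 3L] <- z2[, 3L] + strength * (y == "AC") - strength * (y == "CT")
    z2[y == "AH", 2:3] <- stats::rnorm(sum(y == "AH") * 2L, 0, noise_sd)
    meta <- cbind(softmax(z1), softmax(z2))
    colnames(meta) <- c(paste0("rna_", ALD_CLASSES), paste0("prot_", ALD_CLASSES))
    list(meta = meta, labels = y)
  })
}
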