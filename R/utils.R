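#' @keywords internal
"_PACKAGE"

# Canonical class order used everywhere downstream (probability columns,
# confusion matrices, meta-feature blocks).
ALD_CLASSES <- c("AH", "CT", "AC")

#' Canonical phenotype classes
#'
#' Returns the fixed class order used throughout the package:
#' alcohol-associated hepatitis (`AH`), healthy controls (`CT`),
#' alcohol-associated cirrhosis (`AC`). Probability matrices, confusion
#' matrices and stacked meta-features all use this column order.
#'
#' @return Character vector of length 3.
#' @export
ald_classes <- function() ALD_CLASSES

as_ald_factor <- function(labels) {
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), ALD_CLASSES)
  if (length(bad) > 0L) {
    stop("unknown class label(s): ", paste(bad, collapse = ", "),
         " (expected ", paste(ALD_CLASSES, collapse = "/"), ")")
  }
  factor(labels, levels = ALD_CLASSES)
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state
# afterwards.  Keeps stochastic components (fold plans, simulators, nnet
# weight init) deterministic without clobbering the session RNG.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    # materialize a state so we can restore it
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from (seed, tag) without exceeding .Machine$integer.max.
# Double arithmetic: products stay far below 2^53, the result below 2^31.
child_seed <- function(seed, tag) {
  as.integer((as.numeric(seed) * 1103 + as.numeric(tag) * 7919) %% 2147483629)
}

stopifnot_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    stop("parameter '", name, "' must be a single number in [",
         lower, ", ", upper, "]")
  }
  invisible(x)
}
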