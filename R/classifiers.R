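# Base classifiers over selected, imputed, training-standardized features:
# regularized multinomial logistic regression (nnet::multinom, L2 decay =
# 1/C), one-vs-rest SVM (e1071, linear or RBF; probabilities via softmax
# over the three OVR decision margins), and kNN with neighbour-fraction
# probabilities. All expose predict(type = "prob"/"class") with columns in
# canonical class order.

#' Fit a classifier on selected features
#'
#' Features are standardized with training mean/SD (SD 0 mapped to 1);
#' held-out data reuses the training statistics. Probability rows always
#' sum to 1, columns ordered AH, CT, AC.
#'
#' @param x Numeric matrix, samples x features (already selected and
#'   imputed).
#' @param y Class labels (AH/CT/AC), at least two classes present.
#' @param classifier One of `"kNN"`, `"LR"`, `"SVM-linear"`, `"SVM-rbf"`.
#' @param hyper Classifier hyperparameter: neighbours `k` for kNN, inverse
#'   regularization `C` for LR (decay = 1/C), cost for SVM.
#' @return Object of class `omics_classifier`.
#' @export
fit_classifier <- function(x, y,
                           classifier = c("LR", "kNN", "SVM-linear", "SVM-rbf"),
                           hyper = 1) {
  classifier <- match.arg(classifier)
  y <- as_ald_factor(y)
  present <- levels(droplevels(y))
  if (length(present) < 2L) stop("degenerate training set: only one class present")
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  ctr <- colMeans(x)
  scl <- apply(x, 2L, stats::sd)
  scl[scl == 0 | is.na(scl)] <- 1
  xs <- scale(x, center = ctr, scale = scl)

  fit <- switch(classifier,
    "LR" = {
      df <- data.frame(.y = droplevels(y), xs, check.names = FALSE)
      # zero-seeded init: deterministic regardless of caller RNG state
      with_seed(1L, nnet::multinom(.y ~ ., data = df, decay = 1 / hyper,
                                   trace = FALSE, maxit = 500,
                                   MaxNWts = 100000))
    },
    "kNN" = list(x = xs, y = droplevels(y), k = as.integer(hyper)),
    {
      kern <- if (classifier == "SVM-linear") "linear" else "radial"
      lapply(present, function(cl) {
        yb <- factor(ifelse(y == cl, cl, "rest"), levels = c(cl, "rest"))
        m <- e1071::svm(xs, yb, type = "C-classification", kernel = kern,
                        cost = hyper, scale = FALSE)
        dec <- attr(stats::predict(m, xs, decision.values = TRUE),
                    "decision.values")[, 1L]
        # orient decision values so the target class is positive
        flip <- mean(dec[y == cl]) < mean(dec[y != cl])
        list(model = m, flip = flip)
      }) -> ovr
      names(ovr) <- present
      ovr
    })

  structure(list(classifier = classifier, hyper = hyper, fit = fit,
                 classes = present, features = colnames(x),
                 center = ctr, scale = scl),
            class = "omics_classifier")
}

#' @export
print.omics_classifier <- function(x, ...) {
  cat(sprintf("<omics_classifier> %s (hyper = %s), %d features, classes: %s\n",
              x$classifier, format(x$hyper), length(x$features),
              paste(x$classes, collapse = "/")))
  invisible(x)
}

#' Predict from a fitted classifier
#'
#' @param object An `omics_classifier`.
#' @param newdata Samples x features matrix containing the training
#'   features.
#' @param type `"prob"` for an n x 3 probability matrix (AH, CT, AC) or
#'   `"class"` for hard labels.
#' @param ... Unused.
#' @export
predict.omics_classifier <- function(object, newdata,
                                     type = c("prob", "class"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  miss <- setdiff(object$features, colnames(newdata))
  if (length(miss) > 0L) stop("feature id absent from matrix: ", miss[1L])
  xs <- scale(newdata[, object$features, drop = FALSE],
              center = object$center, scale = object$scale)
  n <- nrow(xs)
  pr <- matrix(0, n, length(ALD_CLASSES), dimnames = list(rownames(xs), ALD_CLASSES))

  if (object$classifier == "LR") {
    df <- data.frame(xs, check.names = FALSE)
    p <- stats::predict(object$fit, newdata = df, type = "probs")
    if (is.null(dim(p))) {
      if (length(object$classes) == 2L) {
        # binary multinom returns P(second level)
        p <- cbind(1 - p, p)
        colnames(p) <- object$classes
      } else {
        p <- matrix(p, nrow = 1L, dimnames = list(NULL, names(p)))
      }
    }
    pr[, colnames(p)] <- p
  } else if (object$classifier == "kNN") {
    tr <- object$fit
    k <- min(tr$k, nrow(tr$x))
    for (i in seq_len(n)) {
      d <- sqrt(colSums((t(tr$x) - xs[i, ])^2))
      nb <- tr$y[order(d)[seq_len(k)]]
      frac <- table(nb) / k
      pr[i, names(frac)] <- as.numeric(frac)
    }
  } else {
    dec <- vapply(object$classes, function(cl) {
      o <- object$fit[[cl]]
      d <- attr(stats::predict(o$model, xs, decision.values = TRUE),
                "decision.values")[, 1L]
      if (o$flip) -d else d
    }, numeric(n))
    if (n == 1L) dec <- matrix(dec, nrow = 1L, dimnames = list(NULL, object$classes))
    e <- exp(dec - apply(dec, 1L, max))
    pr[, object$classes] <- e / rowSums(e)
  }
  pr <- pr / rowSums(pr)
  if (type == "prob") pr else {
    factor(ALD_CLASSES[max.col(pr, ties.method = "first")], levels = ALD_CLASSES)
  }
}

#' Per-class coefficient vectors of a linear classifier
#'
#' For LR the full-class coefficient matrix is reconstructed from the
#' multinomial fit (baseline row zero) and column-centred, giving
#' symmetric per-class vectors; for linear SVM the one-vs-rest primal
#' weights are recovered from the support vectors. Features are on the
#' standardized scale.
#'
#' @param object An `omics_classifier` of type LR or SVM-linear.
#' @param ... Unused.
#' @return Matrix, classes x features.
#' @export
coef.omics_classifier <- function(object, ...) {
  p <- length(object$features)
  if (object$classifier == "LR") {
    cf <- stats::coef(object$fit)
    if (is.null(dim(cf))) cf <- matrix(cf, nrow = 1L, dimnames = list(object$classes[2L], names(cf)))
    W <- matrix(0, length(object$classes), p,
                dimnames = list(object$classes, object$features))
    W[rownames(cf), ] <- cf[, object$features, drop = FALSE]
    sweep(W, 2L, colMeans(W))   # centre: symmetric per-class vectors
  } else if (object$classifier == "SVM-linear") {
    W <- t(vapply(object$classes, function(cl) {
      o <- object$fit[[cl]]
      w <- crossprod(o$model$coefs, o$model$SV)[1L, ]
      full <- numeric(p); names(full) <- object$features
      full[colnames(o$model$SV)] <- w
      if (o$flip) -full else full
    }, numeric(p)))
    rownames(W) <- object$classes
    W
  } else {
    stop("unsupported model: coefficients are defined for LR and SVM-linear only")
  }
}
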