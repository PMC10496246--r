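# R-side wrapper around the compiled SMO solver: full-data one-vs-one
# training, prediction with decision confidences, and stratified folds.

#' Stratified cross-validation fold assignment
#' @param y factor of class labels.
#' @param folds number of folds.
#' @param seed RNG seed (folds are the only stochastic element of CV).
#' @return integer vector of 1-based fold ids, one per sample.
#' @export
make_folds <- function(y, folds = 10, seed = 1) {
  y <- as.factor(y)
  small <- table(y)
  if (any(small < folds))
    nr_stop("noderad_fold_error",
            "class '%s' has %d members < %d folds; reduce the fold count",
            names(small)[which.min(small)], min(small), folds)
  fold <- integer(length(y))
  with_seed(seed, {
    for (cl in levels(y)) {
      idx <- which(y == cl)
      fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
  })
  fold
}

#' Cross-validated accuracy of a one-vs-one RBF SVM
#'
#' Features are z-scored inside each fold using training-fold statistics
#' only. Deterministic given the fold assignment.
#'
#' @param X numeric matrix (samples x features).
#' @param y factor of labels.
#' @param fold integer fold ids from [make_folds()].
#' @param C,gamma SVM cost and RBF kernel width.
#' @return accuracy in \[0, 1\].
#' @export
svm_cv_accuracy <- function(X, y, fold, C = 1, gamma = 1 / ncol(X)) {
  y <- as.factor(y)
  cpp_ovo_cv_accuracy(X, as.integer(y) - 1L, as.integer(fold) - 1L, C, gamma)
}

#' Train a one-vs-one RBF SVM on the full table
#'
#' Columns are z-scored with full-training statistics (stored in the
#' model); one binary C-SVC is solved per class pair.
#'
#' @inheritParams svm_cv_accuracy
#' @param features optional column names to record with the model.
#' @return an object of class `noderad_svm`.
#' @export
svm_train <- function(X, y, C = 1, gamma = 1 / ncol(X), features = colnames(X)) {
  y <- droplevels(as.factor(y))
  k <- nlevels(y)
  if (k < 2) nr_stop("noderad_input_error", "need >= 2 classes")
  ctr <- colMeans(X)
  scl <- apply(X, 2, pop_sd)
  scl[scl < 1e-12] <- 1
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  pairs <- utils::combn(k, 2)
  models <- vector("list", ncol(pairs))
  for (p in seq_len(ncol(pairs))) {
    a <- pairs[1, p]; b <- pairs[2, p]
    sel <- which(as.integer(y) %in% c(a, b))
    ys <- ifelse(as.integer(y)[sel] == a, 1L, -1L)
    K <- cpp_rbf_kernel(Xs[sel, , drop = FALSE], Xs[sel, , drop = FALSE], gamma)
    fit <- cpp_svc_train(K, ys, C)
    sv <- which(fit$alpha > 0)
    models[[p]] <- list(
      classes = c(a, b), trivial = fit$trivial,
      trivial_sign = fit$trivial_sign, b = fit$b,
      sv = Xs[sel[sv], , drop = FALSE],
      coef = fit$alpha[sv] * ys[sv])
  }
  structure(list(levels = levels(y), C = C, gamma = gamma,
                 center = ctr, scale = scl, features = features,
                 pairs = models),
            class = "noderad_svm")
}

#' Predict classes and per-class decision confidence
#' @param model a `noderad_svm`.
#' @param X matrix with the model's feature columns (raw scale).
#' @return list with `class` (factor), `votes` (n x k), `decision`
#'   (n x k summed pairwise decision values).
#' @export
svm_predict <- function(model, X) {
  Xs <- sweep(sweep(X, 2, model$center), 2, model$scale, "/")
  n <- nrow(Xs); k <- length(model$levels)
  votes <- matrix(0, n, k, dimnames = list(NULL, model$levels))
  dsum <- votes
  for (pm in model$pairs) {
    dec <- if (isTRUE(pm$trivial) || nrow(pm$sv) == 0) {
      rep(if (isTRUE(pm$trivial)) pm$trivial_sign else pm$b, n)
    } else {
      as.numeric(cpp_rbf_kernel(Xs, pm$sv, model$gamma) %*% pm$coef + pm$b)
    }
    a <- pm$classes[1]; b <- pm$classes[2]
    w <- ifelse(dec > 0, a, b)
    votes[cbind(seq_len(n), w)] <- votes[cbind(seq_len(n), w)] + 1
    dsum[, a] <- dsum[, a] + dec
    dsum[, b] <- dsum[, b] - dec
  }
  cls <- apply(votes + 1e-9 * dsum, 1, which.max)
  list(class = factor(model$levels[cls], levels = model$levels),
       votes = votes, decision = dsum)
}
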