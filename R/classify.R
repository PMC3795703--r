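# Evaluation protocol: repeated stratified random holdout scored with
# 1-NN under the L1 norm and a linear soft-margin SVM (C-SVC).

#' 1-nearest-neighbor prediction under the L1 norm
#'
#' Each test vector receives the label of the training vector at minimal
#' Manhattan (L1) distance. Ties are broken deterministically in favor of
#' the lowest training-row index.
#'
#' @param train_x Numeric matrix, one training vector per row.
#' @param train_y Labels, one per training row.
#' @param test_x Numeric matrix with the same number of columns.
#' @return Character vector of predicted labels, one per test row.
#' @export
knn_predict <- function(train_x, train_y, test_x) {
  train_x <- as.matrix(train_x)
  test_x <- as.matrix(test_x)
  if (nrow(train_x) == 0L) stop("empty training set")
  if (ncol(train_x) != ncol(test_x)) {
    stop(sprintf("dimension mismatch: train has %d features, test has %d",
                 ncol(train_x), ncol(test_x)))
  }
  if (length(train_y) != nrow(train_x)) {
    stop("train_y must have one label per training row")
  }
  train_y <- as.character(train_y)
  tx <- t(train_x)
  vapply(seq_len(nrow(test_x)), function(i) {
    d <- colSums(abs(tx - test_x[i, ]))
    train_y[which.min(d)]  # which.min takes the first minimum: lowest index
  }, character(1))
}

#' Linear C-SVC prediction
#'
#' Fits a soft-margin support vector classifier with a linear kernel
#' (one-vs-one for multiclass, LIBSVM formulation via \pkg{e1071}) and
#' predicts the test set. Features are not rescaled. Kernel parameters
#' such as degree and coef0 have no effect under a linear kernel and are
#' not exposed.
#'
#' @param train_x,train_y,test_x As in [knn_predict()].
#' @param cost Penalty parameter C of C-SVC (default 100).
#' @return Character vector of predicted labels.
#' @export
svm_predict <- function(train_x, train_y, test_x, cost = 100) {
  train_x <- as.matrix(train_x)
  test_x <- as.matrix(test_x)
  y <- factor(train_y)
  if (nlevels(y) < 2L) stop("SVM training needs at least two classes")
  if (ncol(train_x) != ncol(test_x)) {
    stop(sprintf("dimension mismatch: train has %d features, test has %d",
                 ncol(train_x), ncol(test_x)))
  }
  fit <- e1071::svm(x = train_x, y = y, type = "C-classification",
                    kernel = "linear", cost = cost, scale = FALSE)
  as.character(stats::predict(fit, test_x))
}

#' Stratified random train/test splits
#'
#' Draws `n_repeats` independent splits, each selecting
#' `train_per_class` images per class for training and leaving the rest
#' for testing. The master seed deterministically spawns one sub-seed per
#' repeat (via `sample.int` under the master seed), so a given
#' `(labels, train_per_class, n_repeats, seed)` always yields the same
#' splits — which is how different feature kinds and classifiers are
#' compared on identical training and test samples.
#'
#' @param labels Class labels, one per sample.
#' @param train_per_class Training samples per class.
#' @param n_repeats Number of repeats.
#' @param seed Master seed (integer).
#' @return List of length `n_repeats`; each element has integer index
#'   vectors `train` and `test`.
#' @export
make_splits <- function(labels, train_per_class = 15L, n_repeats = 30L,
                        seed = 1L) {
  labels <- as.character(labels)
  counts <- table(labels)
  if (any(counts < train_per_class + 1L)) {
    bad <- names(counts)[counts < train_per_class + 1L][1L]
    stop(sprintf(
      "class '%s' has %d samples; need at least train_per_class + 1 = %d",
      bad, counts[bad], train_per_class + 1L))
  }
  if (n_repeats < 1L) stop("n_repeats must be >= 1")
  repeat_seeds <- withr::with_seed(
    seed, sample.int(.Machine$integer.max, n_repeats))
  lapply(repeat_seeds, function(s) {
    withr::with_seed(s, {
      train <- unlist(lapply(unique(labels), function(cl) {
        idx <- which(labels == cl)
        sample(idx, train_per_class)
      }), use.names = FALSE)
      list(train = sort(train),
           test = setdiff(seq_along(labels), train))
    })
  })
}

#' Run the repeated-holdout classification experiment
#'
#' For each repeat, a stratified random split is drawn (or taken from
#' `splits`), the classifier is fit on the training rows and scored on the
#' held-out rows, and the accuracy is recorded in percent. The summary is
#' the mean and standard deviation over repeats. The reference protocol is
#' 15 training and 5 test images per class, 30 repeats.
#'
#' @param x Numeric feature matrix or a feature table from
#'   [extract_feature_table()] (its `label`/`id` columns are used).
#' @param labels Class labels (ignored when `x` is a feature table).
#' @param classifier `"knn"` (1-NN, L1) or `"svm"` (linear C-SVC).
#' @param train_per_class,n_repeats,seed Split specification; see
#'   [make_splits()].
#' @param splits Optional precomputed splits, so several feature kinds can
#'   be scored on the same training/test samples.
#' @param cost SVM penalty parameter C.
#' @param scale_features Min-max scale each feature to \[0, 1\] using the
#'   training rows of each split (constant features map to 0). Off by
#'   default: features are raw counts.
#' @return An `mmi_experiment`: list with `accuracy` (per-repeat %),
#'   `mean`, `sd`, and the configuration.
#' @export
run_experiment <- function(x, labels = NULL, classifier = c("knn", "svm"),
                           train_per_class = 15L, n_repeats = 30L,
                           seed = 1L, splits = NULL, cost = 100,
                           scale_features = FALSE) {
  classifier <- match.arg(classifier)
  if (is.data.frame(x)) {
    labels <- labels %||% x$label
    x <- as.matrix(x[, setdiff(names(x), c("label", "id")), drop = FALSE])
  }
  x <- as.matrix(x)
  labels <- as.character(labels)
  if (nrow(x) != length(labels)) stop("one label per feature row required")
  if (is.null(splits)) {
    splits <- make_splits(labels, train_per_class, n_repeats, seed)
  }
  pred_fun <- switch(classifier,
    knn = function(trx, try, tex) knn_predict(trx, try, tex),
    svm = function(trx, try, tex) svm_predict(trx, try, tex, cost = cost))
  acc <- vapply(splits, function(sp) {
    trx <- x[sp$train, , drop = FALSE]
    tex <- x[sp$test, , drop = FALSE]
    if (scale_features) {
      lo <- apply(trx, 2L, min)
      rng <- apply(trx, 2L, max) - lo
      rng[rng == 0] <- 1
      trx <- sweep(sweep(trx, 2L, lo), 2L, rng, "/")
      tex <- sweep(sweep(tex, 2L, lo), 2L, rng, "/")
    }
    pred <- pred_fun(trx, labels[sp$train], tex)
    100 * mean(pred == labels[sp$test])
  }, numeric(1))
  structure(
    list(accuracy = acc,
         mean = mean(acc),
         sd = stats::sd(acc),
         classifier = classifier,
         train_per_class = train_per_class,
         n_repeats = length(splits),
         seed = seed),
    class = "mmi_experiment")
}

#' @export
print.mmi_experiment <- function(x, ...) {
  cat(sprintf("%s: %.4f±%.4f  (accuracy %%, %d repeats, %d train/class)\n",
              toupper(x$classifier), x$mean,
              ifelse(is.na(x$sd), 0, x$sd),
              x$n_repeats, x$train_per_class))
  invisible(x)
}
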