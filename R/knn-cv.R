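# k-nearest-neighbor baseline and the shared cross-validation harness.

knn_predict <- function(train_X, train_y, test_X, k) {
  train_X <- as.matrix(train_X); test_X <- as.matrix(test_X)
  if (k > nrow(train_X)) stop("k exceeds training-fold size")
  lev <- sort(unique(train_y))
  # squared Euclidean distances, vectorized
  d2 <- outer(rowSums(test_X^2), rowSums(train_X^2), "+") -
    2 * tcrossprod(test_X, train_X)
  apply(d2, 1, function(row) {
    nb <- train_y[order(row)[seq_len(k)]]
    votes <- vapply(lev, function(l) sum(nb == l), numeric(1))
    lev[which.max(votes)]  # ties break toward the smaller label index
  })
}

#' Shuffled (unstratified) cross-validation folds
#'
#' Plain shuffled split: n = 4000 with 5 folds gives train/test sizes of
#' 3200/800. Deterministic for a fixed seed; the test sets partition the data.
#'
#' @param n Number of rows.
#' @param folds Number of folds.
#' @param seed Integer seed for the shuffle.
#' @return List of integer vectors, the test indices per fold.
#' @export
make_folds <- function(n, folds = 5L, seed = 1L) {
  if (folds > n) stop("more folds than observations")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  ord <- sample.int(n)
  unname(split(ord, cut(seq_len(n), folds, labels = FALSE)))
}

#' Cross-validate a projection model and refit on the full data
#'
#' Runs plain shuffled k-fold cross-validation for the requested model kind,
#' reporting per-fold train and test accuracies, then refits the final model
#' on all rows (the standard flow: confirm train/test accuracies agree, then
#' train the deployed model on everything).
#'
#' @param X Feature matrix.
#' @param y Binary labels.
#' @param method `"lda"`, `"nn"`, or `"knn"`.
#' @param folds Number of folds (default 5).
#' @param seed Seed for the fold shuffle (and NN init / knn is deterministic).
#' @param ... Passed to the fitting function ([fit_lda()],
#'   [fit_nn_projector()]) or `k` for knn (default 5).
#' @return List with `report` (data.frame: fold, n_train, n_test,
#'   train_accuracy, test_accuracy, seed) and `model` (final refit; for knn,
#'   a list holding the training data and k).
#' @export
cross_validate <- function(X, y, method = c("lda", "nn", "knn"), folds = 5L,
                           seed = 1L, ...) {
  method <- match.arg(method)
  X <- as.matrix(X)
  n <- nrow(X)
  test_sets <- make_folds(n, folds, seed)
  args <- list(...)
  fit_one <- function(Xtr, ytr) {
    switch(method,
      lda = fit_lda(Xtr, ytr),
      nn = do.call(fit_nn_projector, c(list(X = Xtr, y = ytr, seed = seed), args)),
      knn = list(kind = "knn", X = Xtr, y = ytr,
                 k = if (is.null(args$k)) 5L else args$k)
    )
  }
  acc_one <- function(model, Xe, ye) {
    pred <- if (method == "knn") knn_predict(model$X, model$y, Xe, model$k)
            else classify(model, Xe)
    mean(pred == ye)
  }
  report <- do.call(rbind, lapply(seq_along(test_sets), function(i) {
    te <- test_sets[[i]]
    tr <- setdiff(seq_len(n), te)
    m <- fit_one(X[tr, , drop = FALSE], y[tr])
    data.frame(fold = i, n_train = length(tr), n_test = length(te),
               train_accuracy = acc_one(m, X[tr, , drop = FALSE], y[tr]),
               test_accuracy = acc_one(m, X[te, , drop = FALSE], y[te]),
               seed = seed)
  }))
  list(report = report, model = fit_one(X, y))
}

#' k-nearest-neighbor baseline over a range of k
#'
#' Euclidean-metric majority-vote classifier (ties break toward the smaller
#' label index), evaluated by mean test accuracy under shuffled k-fold
#' cross-validation for each k in `k_range`.
#'
#' @param X Feature matrix.
#' @param y Binary labels.
#' @param k_range Integer vector of neighbor counts (default 1:25).
#' @param folds,seed Cross-validation settings.
#' @return Data.frame with one row per k: `k`, `cv_accuracy`.
#' @export
fit_knn_baseline <- function(X, y, k_range = 1:25, folds = 5L, seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (max(k_range) >= n * (folds - 1) / folds) {
    stop("largest k exceeds the training-fold size")
  }
  test_sets <- make_folds(n, folds, seed)
  acc <- vapply(k_range, function(k) {
    mean(vapply(test_sets, function(te) {
      tr <- setdiff(seq_len(n), te)
      pred <- knn_predict(X[tr, , drop = FALSE], y[tr], X[te, , drop = FALSE], k)
      mean(pred == y[te])
    }, numeric(1)))
  }, numeric(1))
  data.frame(k = k_range, cv_accuracy = acc)
}
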