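# Statistical evaluation: Spearman/Pearson correlation with t-based
# significance, Shapiro-Wilk normality gating, Welch two-sided t-tests,
# classification accuracy, and the leave-one-residue-out generalization
# analysis.

cor_t_pvalue <- function(r, n) {
  if (abs(r) >= 1) return(.Machine$double.xmin)
  t <- r * sqrt((n - 2) / (1 - r^2))
  max(2 * stats::pt(-abs(t), df = n - 2), .Machine$double.xmin)
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Average ranks for ties; rho is the Pearson correlation of the ranks; the
#' two-sided p-value comes from `t = rho * sqrt((n-2) / (1-rho^2))` against a
#' t distribution with n-2 degrees of freedom.
#'
#' @param x,y Numeric vectors (n >= 3, finite).
#' @return List with `rho`, `p`, `n`. For a constant input vector `rho` and
#'   `p` are `NA` (undefined).
#' @export
spearman <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 paired finite observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(rho = NA_real_, p = NA_real_, n = n))
  }
  rho <- stats::cor(rank(x), rank(y))
  list(rho = rho, p = cor_t_pvalue(rho, n), n = n)
}

#' Correlation report with Shapiro-Wilk gating of the Pearson coefficient
#'
#' Always reports Spearman; reports Pearson (with its t-test p-value) only
#' when neither variable differs significantly from normality by the
#' Shapiro-Wilk test at level `alpha`. Outside the test's validity range
#' (3 <= n <= 5000) the gate is skipped with a warning and Pearson is
#' omitted.
#'
#' @param x,y Numeric vectors.
#' @param alpha Normality-gate level (default 0.05).
#' @return List: `n`, `spearman_rho`, `spearman_p`, `shapiro_p_x`,
#'   `shapiro_p_y`, and `pearson_r`/`pearson_p` (NA when gated out).
#' @export
pearson_gated <- function(x, y, alpha = 0.05) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  sp <- spearman(x, y)
  out <- list(n = n, spearman_rho = sp$rho, spearman_p = sp$p,
              shapiro_p_x = NA_real_, shapiro_p_y = NA_real_,
              pearson_r = NA_real_, pearson_p = NA_real_)
  if (n < 3 || n > 5000) {
    warning("n outside Shapiro-Wilk validity range; Pearson omitted")
    return(out)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(out)
  out$shapiro_p_x <- stats::shapiro.test(x)$p.value
  out$shapiro_p_y <- stats::shapiro.test(y)$p.value
  if (out$shapiro_p_x >= alpha && out$shapiro_p_y >= alpha) {
    r <- stats::cor(x, y)
    out$pearson_r <- r
    out$pearson_p <- cor_t_pvalue(r, n)
  }
  out
}

#' Two-sided t-test (Welch by default)
#'
#' Independent two-sided Welch t-test; with `paired = TRUE`, a paired t-test.
#' When both groups have zero variance and equal means, `p = 1` by
#' convention (there is no evidence of a difference).
#'
#' @param a,b Numeric vectors (each n >= 2).
#' @param paired Paired test flag.
#' @return List with `t`, `p`, `df`.
#' @export
ttest_two_sided <- function(a, b, paired = FALSE) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (!paired && stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, p = 1, df = length(a) + length(b) - 2))
    return(list(t = sign(mean(a) - mean(b)) * Inf, p = .Machine$double.xmin,
                df = length(a) + length(b) - 2))
  }
  ht <- stats::t.test(a, b, paired = paired, var.equal = FALSE,
                      alternative = "two.sided")
  list(t = unname(ht$statistic), p = ht$p.value, df = unname(ht$parameter))
}

#' Classification accuracy of a projection model
#'
#' @param model A `projection_model` (or a knn model list from
#'   [cross_validate()]).
#' @param X Feature matrix.
#' @param y True binary labels.
#' @return Fraction of correct classifications.
#' @export
classification_accuracy <- function(model, X, y) {
  if (length(y) == 0L) stop("empty evaluation set")
  pred <- if (identical(model$kind, "knn")) {
    knn_predict(model$X, model$y, X, model$k)
  } else {
    classify(model, X)
  }
  mean(pred == y)
}

#' Leave-one-residue-out generalization analysis
#'
#' Trains a model on the variants that lack a given residue at a given site
#' and tests on exactly the variants that carry it (regardless of the other
#' sites). When the training pool exceeds `train_cap`, the most frequently
#' observed variants are kept (positive labels first, mirroring the
#' master-dataset rule when a `frequency` column is present). A one-hot
#' encoder cannot score the held-out residue and is rejected.
#'
#' @param data Data.frame with `sequence`, a label column, and optionally
#'   `frequency` and a continuous truth/measurement column.
#' @param site 1-based sequence position.
#' @param residue The held-out residue.
#' @param label_col Name of the binary label column.
#' @param encoder_kind `"physchem"` or `"embedding"`.
#' @param method Model kind for [cross_validate()]-style fitting
#'   (`"lda"` or `"nn"`).
#' @param truth_col Optional column with continuous measurements or latent
#'   truth; when given, the test-set Spearman rho against the projection is
#'   reported.
#' @param train_cap Maximum training-set size (default 4000).
#' @param weights Embedder weights when `encoder_kind = "embedding"`.
#' @param ... Passed to the fitting function.
#' @return List: `site`, `residue`, `n_train`, `n_test`, `test_accuracy`,
#'   `test_spearman` (NA when no truth column), `model`.
#' @export
leave_one_residue_out <- function(data, site, residue, label_col,
                                  encoder_kind = c("physchem", "embedding"),
                                  method = c("lda", "nn"), truth_col = NULL,
                                  train_cap = 4000L, weights = NULL, ...) {
  encoder_kind <- match.arg(encoder_kind)
  method <- match.arg(method)
  at_site <- substring(data$sequence, site, site) == residue
  if (!any(at_site)) stop("empty test split: residue never observed at site ", site)
  if (all(at_site)) stop("empty training split: residue fixed at site ", site)
  train <- data[!at_site, , drop = FALSE]
  test <- data[at_site, , drop = FALSE]
  if (nrow(train) > train_cap) {
    key <- if ("frequency" %in% names(train)) {
      order(train[[label_col]] != "positive", -train$frequency, train$sequence)
    } else {
      order(train[[label_col]] != "positive", train$sequence)
    }
    train <- train[key[seq_len(train_cap)], , drop = FALSE]
  }
  enc <- feature_encoder(encoder_kind, weights = weights)
  Xtr <- encode_features(enc, train$sequence)
  Xte <- encode_features(enc, test$sequence)
  model <- if (method == "lda") fit_lda(Xtr, train[[label_col]])
           else fit_nn_projector(Xtr, train[[label_col]], ...)
  res <- list(site = site, residue = residue,
              n_train = nrow(train), n_test = nrow(test),
              test_accuracy = classification_accuracy(model, Xte, test[[label_col]]),
              test_spearman = NA_real_, model = model)
  if (!is.null(truth_col)) {
    res$test_spearman <- spearman(project(model, Xte), test[[truth_col]])$rho
  }
  res
}
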