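# Two-class linear discriminant projection model. The fitted direction is the
# Fisher discriminant (pooled within-class covariance inverse times the class
# mean difference), computed through an SVD route so that rank-deficient
# feature matrices (e.g. collinear one-hot blocks) are handled by
# pseudo-inversion with a relative singular-value cutoff.

as_binary_labels <- function(y) {
  if (is.logical(y)) y <- as.integer(y)
  if (is.factor(y)) y <- as.character(y)
  lev <- sort(unique(y))
  if (length(lev) != 2L) stop("exactly two classes required, got ", length(lev))
  list(levels = lev, idx = match(y, lev))  # idx 1 = negative, 2 = positive
}

#' Fit a two-class LDA projection model
#'
#' Computes the Fisher discriminant direction `w` proportional to
#' `Sw^-1 (mu_pos - mu_neg)` via singular value decomposition of the pooled
#' within-class-centered data, dropping singular values below
#' `1e-8 * sigma_max`. The classification threshold is placed where the two
#' Gaussian class discriminant scores are equal (it absorbs the class priors,
#' so it is generally close to, but not exactly, the midpoint). The sign
#' convention guarantees the positive class has the larger mean projection.
#'
#' @param X Numeric feature matrix (rows = variants).
#' @param y Binary labels; the larger level (after sorting) is the positive
#'   class, so 0/1, FALSE/TRUE, and "negative"/"positive" all orient as
#'   expected.
#' @param sv_cutoff Relative singular-value cutoff for the pseudo-inverse.
#' @return An object of class `projection_model` (kind `"lda"`) with fields
#'   `w`, `threshold`, `classes`, and the training projections in
#'   `$training_projections`.
#' @export
fit_lda <- function(X, y, sv_cutoff = 1e-8) {
  X <- as.matrix(X)
  lab <- as_binary_labels(y)
  n <- nrow(X)
  if (length(lab$idx) != n) stop("length(y) must match nrow(X)")
  mu_neg <- colMeans(X[lab$idx == 1L, , drop = FALSE])
  mu_pos <- colMeans(X[lab$idx == 2L, , drop = FALSE])
  d <- mu_pos - mu_neg
  Xc <- X
  Xc[lab$idx == 1L, ] <- sweep(X[lab$idx == 1L, , drop = FALSE], 2, mu_neg)
  Xc[lab$idx == 2L, ] <- sweep(X[lab$idx == 2L, , drop = FALSE], 2, mu_pos)
  sv <- svd(Xc / sqrt(n - 2))
  keep <- sv$d > sv_cutoff * sv$d[1]
  if (sv$d[1] == 0 || !any(keep)) stop("all features constant within classes")
  # w = V diag(1/d^2) V' d  (pseudo-inverse of the pooled covariance)
  V <- sv$v[, keep, drop = FALSE]
  w <- V %*% ((crossprod(V, d)) / sv$d[keep]^2)
  w <- drop(w)
  names(w) <- colnames(X)
  pri <- c(mean(lab$idx == 1L), mean(lab$idx == 2L))
  threshold <- sum(w * (mu_pos + mu_neg)) / 2 + log(pri[1] / pri[2])
  model <- structure(list(
    kind = "lda", w = w, b = 0, threshold = threshold,
    classes = lab$levels, encoder_id = NA_character_,
    feature_names = colnames(X)
  ), class = "projection_model")
  model$training_projections <- project(model, X)
  model
}

#' One-dimensional projection of feature rows
#'
#' The continuous metric of a fitted projection model: an affine map
#' `w . x + b` for LDA, or the single projection-node activation for the
#' neural projector. Values are returned unstandardized.
#'
#' @param model A `projection_model`.
#' @param X Feature matrix encoded with the model's encoder.
#' @return Numeric vector, one value per row of `X`.
#' @export
project <- function(model, X) {
  stopifnot(inherits(model, "projection_model"))
  X <- as.matrix(X)
  if (!is.null(model$feature_names) && !is.null(colnames(X))) {
    if (!identical(colnames(X), model$feature_names)) {
      if (!all(model$feature_names %in% colnames(X))) {
        stop("feature columns do not match the model's encoder")
      }
      X <- X[, model$feature_names, drop = FALSE]
    }
  }
  if (model$kind == "nn") return(nn_forward(model$params, X)$p)
  drop(X %*% model$w) + model$b
}

#' Classify feature rows with a projection model
#'
#' Consistent with the projection by construction:
#' `classify(x) == positive` exactly when `project(x) > threshold`.
#'
#' @inheritParams project
#' @return Vector of class labels (the levels seen at fit time).
#' @export
classify <- function(model, X) {
  p <- project(model, X)
  model$classes[ifelse(p > model$threshold, 2L, 1L)]
}

#' @export
print.projection_model <- function(x, ...) {
  cat(sprintf("<projection_model %s: classes [%s], threshold %.4g>\n",
              x$kind, paste(x$classes, collapse = ", "), x$threshold))
  invisible(x)
}
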