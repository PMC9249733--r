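# Neural projector: two dense hidden layers feeding a single projection node,
# followed by a two-way prediction layer. Trained with softmax cross-entropy
# and ADAM on mini-batches; the scalar projection-node activation is the
# continuous property metric, exactly as for the LDA model.

nn_init_params <- function(d, hidden) {
  sizes <- c(d, hidden, 1L)
  params <- list()
  for (i in seq_len(length(sizes) - 1L)) {
    params[[paste0("W", i)]] <- matrix(stats::rnorm(sizes[i] * sizes[i + 1],
                                                    sd = sqrt(2 / sizes[i])),
                                       sizes[i], sizes[i + 1])
    params[[paste0("b", i)]] <- rep(0, sizes[i + 1])
  }
  # prediction layer: scalar projection -> 2 logits
  params$Wout <- matrix(stats::rnorm(2, sd = 1), 1, 2)
  params$bout <- rep(0, 2)
  params$n_hidden <- length(hidden)
  params
}

nn_forward <- function(params, X) {
  A <- as.matrix(X)
  acts <- list(A)
  nh <- params$n_hidden
  for (i in seq_len(nh)) {
    Z <- sweep(A %*% params[[paste0("W", i)]], 2, -params[[paste0("b", i)]])
    A <- pmax(Z, 0)  # ReLU
    acts[[i + 1L]] <- A
  }
  p <- drop(sweep(A %*% params[[paste0("W", nh + 1L)]], 2,
                  -params[[paste0("b", nh + 1L)]]))  # linear projection node
  logits <- cbind(p * params$Wout[1, 1] + params$bout[1],
                  p * params$Wout[1, 2] + params$bout[2])
  list(p = p, logits = logits, acts = acts)
}

nn_loss_grad <- function(params, X, y_idx) {
  fw <- nn_forward(params, X)
  n <- nrow(as.matrix(X))
  m <- apply(fw$logits, 1, max)
  lse <- m + log(rowSums(exp(fw$logits - m)))
  loss <- mean(lse - fw$logits[cbind(seq_len(n), y_idx)])
  if (!is.finite(loss)) stop("non-finite loss during neural projector training")
  probs <- exp(fw$logits - lse)
  dlogits <- probs
  dlogits[cbind(seq_len(n), y_idx)] <- dlogits[cbind(seq_len(n), y_idx)] - 1
  dlogits <- dlogits / n
  grads <- list()
  grads$Wout <- matrix(colSums(dlogits * fw$p), 1, 2)
  grads$bout <- colSums(dlogits)
  dp <- drop(dlogits %*% t(params$Wout))
  nh <- params$n_hidden
  A <- fw$acts[[nh + 1L]]
  grads[[paste0("W", nh + 1L)]] <- matrix(colSums(A * dp), ncol = 1)
  grads[[paste0("b", nh + 1L)]] <- sum(dp)
  dA <- outer(dp, drop(params[[paste0("W", nh + 1L)]]))
  for (i in rev(seq_len(nh))) {
    dZ <- dA * (fw$acts[[i + 1L]] > 0)
    grads[[paste0("W", i)]] <- crossprod(fw$acts[[i]], dZ)
    grads[[paste0("b", i)]] <- colSums(dZ)
    if (i > 1L) dA <- dZ %*% t(params[[paste0("W", i)]])
  }
  list(loss = loss, grads = grads)
}

#' Fit the neural projector
#'
#' Architecture: two dense ReLU hidden layers (default widths 32 and 8), a
#' single linear projection node, and a two-way softmax prediction layer.
#' Trained with categorical cross-entropy, the ADAM optimizer, and a batch
#' size of 50 for 50 epochs by default (250 is the convention for
#' embedding-feature inputs). Fully seeded: the same data and seed give
#' identical parameters. After training, the projection sign is flipped if
#' needed so larger projections always mean the positive class, and the
#' threshold is the projection value where the two prediction-layer logits
#' are equal.
#'
#' @param X Numeric feature matrix.
#' @param y Binary labels (see [fit_lda()] for orientation).
#' @param hidden Integer vector of hidden-layer widths.
#' @param epochs,batch_size,learning_rate Training schedule.
#' @param seed Integer seed controlling initialization and batch order.
#' @return A `projection_model` of kind `"nn"`.
#' @export
fit_nn_projector <- function(X, y, hidden = c(32L, 8L), epochs = 50L,
                             batch_size = 50L, learning_rate = 1e-3,
                             seed = 1L) {
  X <- as.matrix(X)
  lab <- as_binary_labels(y)
  if (nrow(X) != length(lab$idx)) stop("length(y) must match nrow(X)")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  params <- nn_init_params(ncol(X), hidden)
  pnames <- setdiff(names(params), "n_hidden")
  mstate <- lapply(params[pnames], function(p) p * 0)
  vstate <- mstate
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; step <- 0
  n <- nrow(X)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    for (start in seq(1L, n, by = batch_size)) {
      rows <- ord[start:min(start + batch_size - 1L, n)]
      lg <- nn_loss_grad(params, X[rows, , drop = FALSE], lab$idx[rows])
      step <- step + 1
      for (nm in pnames) {
        g <- lg$grads[[nm]]
        if (is.null(g)) next
        mstate[[nm]] <- b1 * mstate[[nm]] + (1 - b1) * g
        vstate[[nm]] <- b2 * vstate[[nm]] + (1 - b2) * g^2
        mhat <- mstate[[nm]] / (1 - b1^step)
        vhat <- vstate[[nm]] / (1 - b2^step)
        params[[nm]] <- params[[nm]] - learning_rate * mhat / (sqrt(vhat) + eps)
      }
    }
  }
  # orient: positive class logit must increase with the projection
  a <- params$Wout[1, 2] - params$Wout[1, 1]
  if (a < 0) {
    nh <- params$n_hidden
    params[[paste0("W", nh + 1L)]] <- -params[[paste0("W", nh + 1L)]]
    params[[paste0("b", nh + 1L)]] <- -params[[paste0("b", nh + 1L)]]
    params$Wout <- -params$Wout
    a <- -a
  }
  threshold <- if (a == 0) 0 else (params$bout[1] - params$bout[2]) / a
  structure(list(
    kind = "nn", params = params, b = 0, threshold = threshold,
    classes = lab$levels, encoder_id = NA_character_,
    feature_names = colnames(X),
    config = list(hidden = hidden, epochs = epochs, batch_size = batch_size,
                  learning_rate = learning_rate, seed = seed)
  ), class = "projection_model")
}
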