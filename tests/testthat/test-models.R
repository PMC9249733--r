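test_that("LDA separates well-separated clusters with a meaningful threshold", {
  tc <- toy_clusters()
  m <- fit_lda(tc$X, tc$y)
  expect_equal(classification_accuracy(m, tc$X, tc$y), 1.0)
  proj <- project(m, tc$X)
  expect_true(all(proj[tc$y == "positive"] > m$threshold))
  expect_true(all(proj[tc$y == "negative"] <= m$threshold))
  # class-mean of positives projects above threshold
  mu_pos <- colMeans(tc$X[tc$y == "positive", , drop = FALSE])
  expect_gt(project(m, matrix(mu_pos, 1)), m$threshold)
  # training projections are reproduced exactly
  expect_identical(proj, m$training_projections)
})

test_that("LDA direction matches the closed-form pooled-covariance solution", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 200; d <- sample(3:8, 1)
    X <- matrix(rnorm(n * d), n, d)
    y <- rep(0:1, each = n / 2)
    X[y == 1, ] <- X[y == 1, ] + rep(runif(d, 0.3, 1), each = n / 2)
    m <- fit_lda(X, y)
    mu0 <- colMeans(X[y == 0, ]); mu1 <- colMeans(X[y == 1, ])
    Xc <- X
    Xc[y == 0, ] <- sweep(X[y == 0, ], 2, mu0)
    Xc[y == 1, ] <- sweep(X[y == 1, ], 2, mu1)
    w_ref <- solve(crossprod(Xc) / (n - 2), mu1 - mu0)
    expect_equal(m$w / sqrt(sum(m$w^2)),
                 unname(w_ref / sqrt(sum(w_ref^2))),
                 tolerance = 1e-6)
  }
})

test_that("LDA direction agrees with MASS::lda as an independent reference", {
  set.seed(19)
  n <- 240; d <- 5
  X <- matrix(rnorm(n * d), n, d)
  y <- rep(c("negative", "positive"), each = n / 2)
  X[y == "positive", ] <- X[y == "positive", ] + rep(seq(0.3, 1, length.out = d), each = n / 2)
  m <- fit_lda(X, y)
  ref <- MASS::lda(X, grouping = y)
  w_ref <- drop(ref$scaling)
  # same direction up to sign/scale (MASS sphers to unit within-class variance)
  cos_angle <- sum(m$w * w_ref) / sqrt(sum(m$w^2) * sum(w_ref^2))
  expect_equal(abs(cos_angle), 1, tolerance = 1e-8)
  # identical classifications on the training data
  expect_equal(classify(m, X), as.character(predict(ref, X)$class))
})

test_that("LDA direction is invariant to duplicating every sample", {
  set.seed(7)
  X <- matrix(rnorm(60 * 4), 60, 4)
  y <- rep(c("negative", "positive"), 30)
  X[y == "positive", 1] <- X[y == "positive", 1] + 2
  m1 <- fit_lda(X, y)
  m2 <- fit_lda(rbind(X, X), c(y, y))
  expect_equal(m1$w / sqrt(sum(m1$w^2)), m2$w / sqrt(sum(m2$w^2)),
               tolerance = 1e-8)
})

test_that("label flip negates projections and preserves accuracy; classify matches threshold", {
  set.seed(10)
  X <- matrix(rnorm(100 * 3), 100, 3)
  y <- rep(0:1, 50)
  X[y == 1, ] <- X[y == 1, ] + 1.5
  m <- fit_lda(X, y)
  m_flip <- fit_lda(X, 1 - y)
  expect_equal(project(m_flip, X), -project(m, X), tolerance = 1e-8)
  expect_equal(classification_accuracy(m, X, y),
               classification_accuracy(m_flip, X, 1 - y))
  expect_identical(classify(m, X) == "1", project(m, X) > m$threshold)
})

test_that("LDA handles rank-deficient one-hot input and rejects degenerate input", {
  set.seed(14)
  seqs <- sample_library_variants(tiny_design(), 30)
  enc <- onehot_fit(seqs)
  X <- onehot_encode(enc, seqs)  # collinear blocks + constant columns
  y <- rep(c("negative", "positive"), 15)
  expect_silent(m <- fit_lda(X, y))
  expect_length(project(m, X), 30L)
  expect_error(fit_lda(X, rep("positive", 30)), "two classes")
  expect_error(fit_lda(matrix(1, 20, 3), rep(0:1, 10)), "constant")
})

test_that("neural projector yields scalar projections, learns a separable set, and is seeded", {
  tc <- toy_clusters(n_per = 30)
  m <- fit_nn_projector(tc$X, tc$y, epochs = 50, seed = 3)
  p <- project(m, tc$X)
  expect_length(p, 60L)
  expect_equal(classification_accuracy(m, tc$X, tc$y), 1.0)
  expect_identical(classify(m, tc$X) == "positive", p > m$threshold)
  # sign convention: positive class has the larger mean projection
  expect_gt(mean(p[tc$y == "positive"]), mean(p[tc$y == "negative"]))
  # same data + same seed -> identical parameters
  m2 <- fit_nn_projector(tc$X, tc$y, epochs = 50, seed = 3)
  expect_identical(m$params, m2$params)
  m3 <- fit_nn_projector(tc$X, tc$y, epochs = 50, seed = 4)
  expect_false(identical(m$params, m3$params))
})

test_that("knn baseline reports one row per k and matches brute-force voting", {
  tc <- toy_clusters(n_per = 25)
  rep_knn <- fit_knn_baseline(tc$X, tc$y, k_range = 1:25, seed = 2)
  expect_equal(nrow(rep_knn), 25L)
  expect_equal(rep_knn$cv_accuracy[rep_knn$k == 1], 1.0)
  # k = n -> constant majority-class prediction
  set.seed(30)
  Xtr <- matrix(rnorm(20 * 2), 20, 2)
  ytr <- c(rep("a", 12), rep("b", 8))
  pred <- abpareto:::knn_predict(Xtr, ytr, matrix(rnorm(10 * 2), 10, 2), k = 20)
  expect_true(all(pred == "a"))
  # tie-break toward the smaller label index
  pred_tie <- abpareto:::knn_predict(matrix(c(0, 0, 1, 1), 2, 2), c("a", "b"),
                                     matrix(c(0.5, 0.5), 1, 2), k = 2)
  expect_equal(pred_tie, "a")
  expect_error(fit_knn_baseline(tc$X, tc$y, k_range = 1:60), "exceeds")
})

test_that("cross-validation folds partition the data with the quoted sizes", {
  folds <- make_folds(4000, 5, seed = 1)
  expect_equal(lengths(folds), rep(800L, 5))
  expect_setequal(unlist(folds), 1:4000)
  expect_equal(lengths(make_folds(10, 5, seed = 1)), rep(2L, 5))
  expect_identical(make_folds(100, 5, seed = 9), make_folds(100, 5, seed = 9))
  expect_error(make_folds(3, 5), "folds")

  tc <- toy_clusters(n_per = 50)
  cv <- cross_validate(tc$X, tc$y, "lda", folds = 5, seed = 11)
  expect_equal(cv$report$n_train, rep(80L, 5))
  expect_equal(cv$report$n_test, rep(20L, 5))
  expect_true(all(cv$report$test_accuracy == 1))
  expect_s3_class(cv$model, "projection_model")
})
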