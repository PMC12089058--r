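make_blobs <- function(n_per_class = 100, sep = 6, p = 4, seed = 51) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per_class * p), ncol = p),
             matrix(rnorm(n_per_class * p, mean = sep), ncol = p))
  y <- rep(c("visualization", "workload"), each = n_per_class)
  list(X = X, y = y)
}

test_that("hyperparameter grids have the fixed cardinalities", {
  expect_equal(length(model_grid("SVM_LINEAR")), 3)
  expect_equal(length(model_grid("KNN")), 4)
  expect_equal(length(model_grid("QDA")), 3)
  expect_equal(length(model_grid("ANN")), 2)
  expect_equal(length(model_grid("RF")), 4)
  expect_equal(length(model_grid("LDA")), 1)
  expect_equal(vapply(model_grid("SVM_LINEAR"), `[[`, numeric(1), "C"),
               c(0.1, 1, 10))
  expect_equal(vapply(model_grid("KNN"), `[[`, numeric(1), "k"),
               c(3, 5, 7, 9))
  expect_equal(vapply(model_grid("QDA"), `[[`, numeric(1), "reg"),
               c(0.1, 0.5, 1))
  expect_equal(vapply(model_grid("ANN"), `[[`, numeric(1), "size"),
               c(10, 50))
  expect_equal(vapply(model_grid("RF"), `[[`, numeric(1), "ntree"),
               c(10, 50, 100, 200))
})

test_that("every family separates well-separated blobs on its training set", {
  blobs <- make_blobs()
  for (family in c("SVM_LINEAR", "KNN", "LDA", "QDA", "ANN", "RF")) {
    model <- fit_classifier(blobs$X, blobs$y, family,
                            model_grid(family)[[1]], seed = 52)
    pred <- predict(model, blobs$X)
    cm <- confusion_counts(blobs$y, pred)
    expect_gte(metrics_from_confusion(cm)$macro_f1, 0.99)
  }
})

test_that("KNN assigns a training point its own label", {
  blobs <- make_blobs(n_per_class = 30, sep = 3)
  model <- fit_classifier(blobs$X, blobs$y, "KNN", list(k = 3), seed = 53)
  pred <- predict(model, blobs$X[c(1, 31), , drop = FALSE])
  expect_equal(as.character(pred), c("visualization", "workload"))
})

test_that("stochastic families are deterministic under a fixed seed", {
  blobs <- make_blobs(n_per_class = 40, sep = 1.5)
  Xt <- make_blobs(n_per_class = 25, sep = 1.5, seed = 99)$X
  for (family in c("RF", "ANN")) {
    m1 <- fit_classifier(blobs$X, blobs$y, family,
                         model_grid(family)[[1]], seed = 54)
    m2 <- fit_classifier(blobs$X, blobs$y, family,
                         model_grid(family)[[1]], seed = 54)
    expect_identical(predict(m1, Xt), predict(m2, Xt))
  }
  # repeated prediction from the same model is identical
  m <- fit_classifier(blobs$X, blobs$y, "KNN", list(k = 5), seed = 54)
  expect_identical(predict(m, Xt), predict(m, Xt))
})

test_that("fully regularised QDA agrees with LDA on spherical classes", {
  set.seed(55)
  n <- 2000; p <- 2
  X <- rbind(matrix(rnorm(n * p), ncol = p),
             matrix(rnorm(n * p, mean = 2), ncol = p))
  y <- rep(c("visualization", "workload"), each = n)
  qda_m <- fit_classifier(X, y, "QDA", list(reg = 1), seed = 56)
  lda_m <- fit_classifier(X, y, "LDA", seed = 56)
  grid <- as.matrix(expand.grid(seq(-1.5, 3.5, 0.2), seq(-1.5, 3.5, 0.2)))
  pq <- predict(qda_m, grid)
  pl <- predict(lda_m, grid)
  # identical-covariance limit: boundaries agree except at near-ties
  expect_gt(mean(pq == pl), 0.97)
})

test_that("permuted labels give chance-level held-out performance", {
  set.seed(57)
  X <- matrix(rnorm(400 * 6), 400, 6)
  f1s <- vapply(1:5, function(i) {
    set.seed(500 + i)
    y <- sample(rep(c("visualization", "workload"), each = 200))
    tr <- 1:300
    model <- fit_classifier(X[tr, ], y[tr], "SVM_LINEAR", list(C = 1),
                            seed = i)
    pred <- predict(model, X[-tr, ])
    metrics_from_confusion(confusion_counts(y[-tr], pred))$macro_f1
  }, numeric(1))
  expect_gt(mean(f1s), 0.4)
  expect_lt(mean(f1s), 0.6)
})

test_that("fit and predict validate their inputs", {
  blobs <- make_blobs(n_per_class = 20)
  expect_error(fit_classifier(blobs$X, rep("visualization", 40), "SVM_LINEAR"),
               "every class")
  expect_error(fit_classifier(blobs$X, blobs$y[1:10], "SVM_LINEAR"),
               "dimension")
  m <- fit_classifier(blobs$X, blobs$y, "SVM_LINEAR")
  expect_error(predict(m, blobs$X[, 1:2]), "dimension")
})
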