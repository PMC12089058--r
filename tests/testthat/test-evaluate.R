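test_that("F1 arithmetic reproduces published per-class values", {
  # harmonic mean of precision 1.000 and recall 0.929
  p <- 1.000; r <- 0.929
  expect_equal(2 * p * r / (p + r), 0.963, tolerance = 5e-4)
  # macro precision of a participant with per-class precisions 1.000, 0.824
  expect_equal(mean(c(1.000, 0.824)), 0.912, tolerance = 5e-4)
  # the same numbers through the confusion-matrix path:
  # 89 visualization and 82 workload windows correct, 31 and 38 confused
  cm <- matrix(c(89, 31, 38, 82), 2, byrow = TRUE,
               dimnames = list(c("visualization", "workload"),
                               c("visualization", "workload")))
  m <- metrics_from_confusion(cm)
  expect_equal(m$per_class$f1[1], 0.721, tolerance = 5e-4)
  expect_equal(m$per_class$f1[2], 0.704, tolerance = 5e-4)
  expect_equal(m$n, 240)
})

test_that("degenerate and perfect confusion matrices follow the conventions", {
  perfect <- diag(c(10, 14))
  m <- metrics_from_confusion(perfect)
  expect_equal(m$macro_f1, 1.0)
  expect_equal(m$macro_precision, 1.0)
  expect_equal(m$macro_recall, 1.0)
  # one class never predicted: its precision and F1 are 0, not NaN
  cm <- matrix(c(10, 0, 5, 0), 2, byrow = TRUE)
  m2 <- metrics_from_confusion(cm)
  expect_equal(m2$per_class$precision[2], 0)
  expect_equal(m2$per_class$f1[2], 0)
  expect_false(anyNA(unlist(m2$per_class[, -1])))
  expect_error(metrics_from_confusion(matrix(0, 2, 2)), "no counts")
  expect_error(metrics_from_confusion(matrix(1, 2, 3)), "square")
})

test_that("metrics agree with a brute-force loop on random confusion matrices", {
  brute <- function(cm) {
    K <- nrow(cm)
    prec <- rec <- f1 <- numeric(K)
    for (i in seq_len(K)) {
      tp <- cm[i, i]
      fp <- 0; fn <- 0
      for (j in seq_len(K)) {
        if (j != i) {
          fp <- fp + cm[j, i]
          fn <- fn + cm[i, j]
        }
      }
      prec[i] <- if (tp + fp > 0) tp / (tp + fp) else 0
      rec[i] <- if (tp + fn > 0) tp / (tp + fn) else 0
      f1[i] <- if (prec[i] + rec[i] > 0)
        2 * prec[i] * rec[i] / (prec[i] + rec[i]) else 0
    }
    c(mean(prec), mean(rec), mean(f1))
  }
  set.seed(61)
  for (rep in 1:200) {
    K <- sample(2:4, 1)
    cm <- matrix(rpois(K * K, 5), K, K)
    if (sum(cm) == 0) cm[1, 1] <- 1
    m <- metrics_from_confusion(cm)
    expect_equal(c(m$macro_precision, m$macro_recall, m$macro_f1),
                 brute(cm), tolerance = 1e-12)
  }
})

test_that("participant aggregation reproduces the published mean and spread", {
  scores <- c(0.892, 0.222, 0.333, 0.964, 0.317, 0.388, 0.263, 0.750)
  agg <- aggregate_participants(scores)
  expect_equal(agg$mean, 0.516, tolerance = 5e-4)
  # population (n-normalised) standard deviation
  expect_equal(agg$sd, 0.282, tolerance = 5e-4)
  expect_equal(aggregate_participants(rep(0.7, 5))$sd, 0)
  expect_error(aggregate_participants(numeric(0)), "empty")
})

test_that("window sweep summary computes row means and rejects holes", {
  df <- expand.grid(family = c("RF", "SVM_LINEAR"),
                    window = c(50, 100, 150, 200, 250, 300),
                    stringsAsFactors = FALSE)
  f1 <- c(0.590, 0.690, 0.650, 0.680, 0.680, 0.710)
  df$macro_f1 <- ifelse(df$family == "RF", f1[match(df$window, c(50, 100, 150, 200, 250, 300))], 0.5)
  tab <- summarize_window_sweep(df)
  expect_equal(unname(tab["RF", "Mean"]), 0.667, tolerance = 5e-4)
  expect_equal(unname(tab["SVM_LINEAR", "Mean"]), 0.5)
  # constant row -> mean equals the constant
  expect_true(all(tab["SVM_LINEAR", ] == 0.5))
  # a missing cell is an error, not silent NaN
  expect_error(summarize_window_sweep(df[-3, ]), "missing")
})
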