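test_that("window durations follow frames / fs", {
  expect_equal(100 / 5.8, 17.24, tolerance = 3e-4)
  s <- quick_session(seed = 41)
  wins <- segment_windows(s, 100)
  expect_true(all(wins$end - wins$start + 1 == 100))
  expect_equal(300 / 5.8, 51.72, tolerance = 1e-4)
})

test_that("segmentation drops partial windows and never mixes tasks", {
  s <- quick_session(seed = 42)  # 60 s blocks -> 348 frames per task block
  wins <- segment_windows(s, 100)
  # floor(348/100) = 3 windows per task block, 6 task blocks
  expect_equal(nrow(wins), 18)
  expect_true(all(table(wins$block) == 3))
  for (i in seq_len(nrow(wins))) {
    lab <- s$labels[wins$start[i]:wins$end[i]]
    expect_equal(length(unique(lab)), 1)
    expect_equal(unique(lab), wins$task[i])
  }
  # rest blocks are never windowed
  expect_false(any(wins$task == "rest"))
  # group restriction
  w12 <- segment_windows(s, 100, groups = 1:2)
  expect_setequal(unique(w12$group), 1:2)
  # window longer than every block errors
  expect_error(segment_windows(s, 10000), "longer")
})

test_that("per-channel statistics match closed forms", {
  fs <- 5.8
  # constant window
  const <- matrix(3.5, 50, 2, dimnames = list(NULL, c("a", "b")))
  f <- extract_features(const, c("max", "mean", "sd", "skew", "slope"), fs)
  expect_equal(unname(f[c("a_max", "a_mean")]), c(3.5, 3.5))
  expect_equal(unname(f[c("a_sd", "a_skew", "a_slope")]), c(0, 0, 0))
  # ramp at 1 unit per second
  n <- 100
  ramp <- matrix((0:(n - 1)) / fs, ncol = 1, dimnames = list(NULL, "r"))
  fr <- extract_features(ramp, "slope", fs)
  expect_equal(unname(fr["r_slope"]), 1.0, tolerance = 1e-12)
  # small arithmetic example
  w <- matrix(c(1, 2, 3, 10), ncol = 1, dimnames = list(NULL, "x"))
  fx <- extract_features(w, c("max", "mean"), fs)
  expect_equal(unname(fx), c(10, 4))
  # skewness agrees with the moment definition on random data
  set.seed(43)
  v <- matrix(rexp(500), ncol = 1, dimnames = list(NULL, "v"))
  fs_v <- extract_features(v, "skew", fs)
  m <- mean(v); s3 <- mean((v - m)^3) / mean((v - m)^2)^1.5
  expect_equal(unname(fs_v), s3)
  expect_error(extract_features(matrix(nrow = 0, ncol = 1), "mean"), "empty")
})

test_that("feature table has channels x statistics layout", {
  s <- quick_session(seed = 44)
  ft <- build_feature_table(s, 100, c("max", "mean"))
  # 6 long positions x 2 chromophores x 2 statistics = 24 features
  expect_equal(ncol(ft$X), 24)
  expect_equal(nrow(ft$X), 18)
  expect_s3_class(ft$y, "factor")
  expect_equal(levels(ft$y), c("visualization", "workload"))
  expect_true(all(grepl("_(max|mean)$", ft$feature_names)))
  # no short channels among the features
  expect_false(any(grepl("P7|P8", ft$feature_names)))
})

test_that("scaler standardises training rows and freezes its parameters", {
  set.seed(45)
  X <- matrix(rnorm(200, mean = 5, sd = 3), 20, 10)
  sc <- fit_scaler(X)
  Xs <- apply_scaler(sc, X)
  expect_true(all(abs(colMeans(Xs)) < 1e-10))
  expect_equal(unname(apply(Xs, 2, sd)), rep(1, 10))
  # a test row equal to the training mean maps to zero
  expect_equal(as.numeric(apply_scaler(sc, matrix(sc$mean, 1))),
               rep(0, 10))
  # deliberately not idempotent: second application rescales again
  Xss <- apply_scaler(sc, Xs)
  expect_false(isTRUE(all.equal(Xs, Xss)))
  # constant features are flagged and centred only
  Xc <- cbind(X, 7)
  sc2 <- fit_scaler(Xc)
  expect_true(sc2$constant[11])
  expect_equal(unname(apply_scaler(sc2, Xc)[, 11]), rep(0, 20))
})

test_that("F-test selection matches the anova oracle and ranks signal first", {
  set.seed(46)
  n <- 60
  y <- rep(c("visualization", "workload"), each = n / 2)
  X <- matrix(rnorm(n * 24), n, 24)
  X[, 7] <- as.numeric(factor(y)) + rnorm(n, 0, 0.1)  # spiked feature
  sel <- select_k_best(X, y, k = 10)
  # oracle: explicit one-way ANOVA per feature
  f_oracle <- vapply(seq_len(ncol(X)), function(j) {
    anova(lm(X[, j] ~ factor(y)))$`F value`[1]
  }, numeric(1))
  expect_equal(sel$f_stat, f_oracle, tolerance = 1e-10)
  expect_true(7 %in% sel$indices)
  expect_equal(which.max(sel$f_stat), 7L)
  expect_equal(length(sel$indices), 10)
  # K >= n_features keeps everything
  sel_all <- select_k_best(X, y, k = 100)
  expect_equal(sel_all$indices, seq_len(24))
  expect_error(select_k_best(X, rep("visualization", n)), "2 classes")
})

test_that("selection under permuted labels is unstable across seeds", {
  set.seed(47)
  X <- matrix(rnorm(60 * 24), 60, 24)
  picks <- lapply(1:5, function(i) {
    set.seed(100 + i)
    y <- sample(rep(c("visualization", "workload"), each = 30))
    select_k_best(X, y, k = 10)$indices
  })
  # pure-noise features: different permutations select different sets
  expect_gt(length(unique(picks)), 1)
})
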