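MODEL_FAMILIES <- c("SVM_LINEAR", "KNN", "LDA", "QDA", "ANN", "RF")

#' Hyperparameter grid for a classifier family
#'
#' Returns the fixed tuning grid of each family, ordered ascending so that
#' ties in model selection resolve to the smallest value:
#' linear SVM `C in (0.1, 1, 10)`; KNN `k in (3, 5, 7, 9)`; QDA
#' regularization `r in (0.1, 0.5, 1)`; ANN hidden layer size `in (10, 50)`
#' (5000 max iterations); random forest `ntree in (10, 50, 100, 200)`;
#' LDA has no tunable parameter.
#'
#' @param family One of `"SVM_LINEAR"`, `"KNN"`, `"LDA"`, `"QDA"`, `"ANN"`,
#'   `"RF"`.
#' @return List of named parameter lists (length 1 for LDA).
#' @export
model_grid <- function(family) {
  family <- match.arg(family, MODEL_FAMILIES)
  switch(family,
    SVM_LINEAR = lapply(c(0.1, 1, 10), function(C) list(C = C)),
    KNN = lapply(c(3, 5, 7, 9), function(k) list(k = k)),
    LDA = list(list()),
    QDA = lapply(c(0.1, 0.5, 1), function(r) list(reg = r)),
    ANN = lapply(c(10, 50), function(s) list(size = s)),
    RF = lapply(c(10, 50, 100, 200), function(nt) list(ntree = nt))
  )
}

#' Fit a classifier with a uniform contract
#'
#' Trains one of the six supported classifier families on a feature matrix.
#' All families share the same interface and are deterministic given `seed`.
#' The online-pipeline default is the linear SVM with `C = 1` (1000 max
#' iterations in the reference implementation's parameterisation).
#'
#' Families: `SVM_LINEAR` (e1071, linear kernel, cost `C`); `KNN` (class
#' package, Euclidean, uniform weights, `use.all` for distance ties); `LDA`
#' (MASS); `QDA` (in-package regularised Gaussian discriminant with
#' \eqn{\Sigma_r = (1-r)\Sigma + rI}); `ANN` (nnet, single hidden layer
#' of `size` units, 5000 max iterations); `RF` (randomForest, Gini
#' impurity, `ntree` trees).
#'
#' @param X Numeric training matrix (rows = windows).
#' @param y Labels, coercible to a factor with the fixed class order
#'   (visualization, workload); at least one row per class.
#' @param family Classifier family, see [model_grid()].
#' @param params Named list of hyperparameters for the family.
#' @param seed Integer seed controlling any training randomness.
#' @return Object of class `nirs_classifier` with a [predict][
#'   predict.nirs_classifier] method.
#' @export
fit_classifier <- function(X, y, family = "SVM_LINEAR",
                           params = list(), seed = 1L) {
  family <- match.arg(family, MODEL_FAMILIES)
  X <- as.matrix(X)
  lv <- if (all(y %in% TASK_LEVELS)) TASK_LEVELS else sort(unique(as.character(y)))
  y <- factor(as.character(y), levels = lv)
  if (nrow(X) != length(y)) stop("dimension mismatch between X and y")
  if (any(table(y) == 0)) stop("training set must contain every class")
  set.seed(seed)
  fit <- switch(family,
    SVM_LINEAR = e1071::svm(x = X, y = y, kernel = "linear",
                            cost = params$C %||% 1, scale = FALSE),
    KNN = list(X = X, y = y, k = params$k %||% 3),
    LDA = MASS::lda(X, grouping = y),
    QDA = fit_rqda(X, y, params$reg %||% 0.5),
    ANN = {
      df <- data.frame(X, check.names = FALSE)
      colnames(df) <- paste0("f", seq_len(ncol(X)))
      df$.y <- y
      nnet::nnet(.y ~ ., data = df, size = params$size %||% 10,
                 maxit = 5000, trace = FALSE, MaxNWts = 100000)
    },
    RF = randomForest::randomForest(x = X, y = y,
                                    ntree = params$ntree %||% 100)
  )
  structure(
    list(family = family, params = params, seed = as.integer(seed),
         fit = fit, levels = lv, p = ncol(X), n_train = nrow(X)),
    class = "nirs_classifier"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Regularised quadratic discriminant: per class, Gaussian with sample mean
## and covariance shrunk toward the identity (features are standardised
## upstream, so the identity target is on the right scale).
fit_rqda <- function(X, y, reg) {
  stopifnot(reg >= 0, reg <= 1)
  classes <- levels(y)
  comps <- lapply(classes, function(cl) {
    Xc <- X[y == cl, , drop = FALSE]
    if (nrow(Xc) < 2) stop("each class needs >= 2 rows for QDA")
    S <- stats::cov(Xc)
    Sr <- (1 - reg) * S + reg * diag(ncol(X))
    list(mu = colMeans(Xc),
         prec = solve(Sr),
         logdet = as.numeric(determinant(Sr, logarithm = TRUE)$modulus),
         logprior = log(nrow(Xc) / nrow(X)))
  })
  names(comps) <- classes
  list(reg = reg, classes = classes, comps = comps)
}

predict_rqda <- function(fit, X) {
  scores <- sapply(fit$classes, function(cl) {
    cm <- fit$comps[[cl]]
    d <- sweep(X, 2, cm$mu)
    -0.5 * rowSums((d %*% cm$prec) * d) - 0.5 * cm$logdet + cm$logprior
  })
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1)
  fit$classes[max.col(scores, ties.method = "first")]
}

#' Predict task labels
#'
#' @param object A fitted `nirs_classifier`.
#' @param newdata Numeric matrix with the training feature dimension.
#' @param ... Unused.
#' @return Factor of predicted labels (levels as at training time).
#' @export
predict.nirs_classifier <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (ncol(X) != object$p) stop("dimension mismatch: expected ", object$p,
                                " features, got ", ncol(X))
  out <- switch(object$family,
    SVM_LINEAR = as.character(stats::predict(object$fit, X)),
    KNN = {
      set.seed(object$seed)  # deterministic distance-tie handling
      as.character(class::knn(object$fit$X, X, object$fit$y,
                              k = object$fit$k, use.all = TRUE))
    },
    LDA = {
      colnames(X) <- colnames(object$fit$means)
      as.character(stats::predict(object$fit, X)$class)
    },
    QDA = predict_rqda(object$fit, X),
    ANN = {
      df <- data.frame(X, check.names = FALSE)
      colnames(df) <- paste0("f", seq_len(ncol(X)))
      as.character(stats::predict(object$fit, df, type = "class"))
    },
    RF = {
      set.seed(object$seed)  # deterministic vote-tie handling
      as.character(stats::predict(object$fit, X))
    }
  )
  factor(out, levels = object$levels)
}

#' @export
print.nirs_classifier <- function(x, ...) {
  ps <- if (length(x$params)) {
    paste(names(x$params), unlist(x$params), sep = "=", collapse = ", ")
  } else "defaults"
  cat("nirs_classifier:", x$family, "(", ps, "), trained on", x$n_train,
      "windows x", x$p, "features\n")
  invisible(x)
}
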