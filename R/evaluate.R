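#' Confusion matrix of task predictions
#'
#' @param truth True labels.
#' @param pred Predicted labels.
#' @param levels Class order (default visualization, workload).
#' @return K x K integer matrix of counts, rows = true class, columns =
#'   predicted class.
#' @export
confusion_counts <- function(truth, pred, levels = TASK_LEVELS) {
  truth <- factor(as.character(truth), levels = levels)
  pred <- factor(as.character(pred), levels = levels)
  stopifnot(length(truth) == length(pred))
  as.matrix(table(true = truth, predicted = pred))
}

#' Per-class and macro precision, recall and F1 from a confusion matrix
#'
#' For class \eqn{i}: precision \eqn{P_i = TP_i / (TP_i + FP_i)}, recall
#' \eqn{R_i = TP_i / (TP_i + FN_i)}, \eqn{F1_i = 2 P_i R_i / (P_i + R_i)}.
#' Macro metrics are the unweighted means over the K classes. Any 0/0 is
#' defined as 0 (degenerate folds where a class is never predicted or never
#' present report 0.000, matching the reporting convention of real-time BCI
#' result tables).
#'
#' @param cm K x K count matrix, rows = true class, columns = predicted.
#' @return Object of class `nirs_metrics`: list with `per_class` (data frame
#'   `class`, `precision`, `recall`, `f1`), `macro_precision`,
#'   `macro_recall`, `macro_f1`, `n`, `confusion`.
#' @examples
#' cm <- matrix(c(89, 31, 38, 82), 2, byrow = TRUE,
#'              dimnames = list(c("visualization", "workload"),
#'                              c("visualization", "workload")))
#' metrics_from_confusion(cm)
#' @export
metrics_from_confusion <- function(cm) {
  cm <- as.matrix(cm)
  if (length(cm) == 0 || nrow(cm) != ncol(cm)) stop("empty or non-square confusion matrix")
  if (sum(cm) == 0) stop("confusion matrix has no counts")
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  safe_div <- function(a, b) ifelse(b > 0, a / b, 0)
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  f1 <- safe_div(2 * precision * recall, precision + recall)
  classes <- rownames(cm)
  if (is.null(classes)) classes <- paste0("class", seq_len(nrow(cm)))
  structure(
    list(
      per_class = data.frame(class = classes, precision = precision,
                             recall = recall, f1 = f1, row.names = NULL,
                             stringsAsFactors = FALSE),
      macro_precision = mean(precision),
      macro_recall = mean(recall),
      macro_f1 = mean(f1),
      n = sum(cm),
      confusion = cm
    ),
    class = "nirs_metrics"
  )
}

#' @export
print.nirs_metrics <- function(x, digits = 3, ...) {
  cat("Classification metrics over", x$n, "windows\n")
  pc <- x$per_class
  pc[, -1] <- round(pc[, -1], digits)
  print(pc, row.names = FALSE)
  cat(sprintf("macro: precision %.3f  recall %.3f  F1 %.3f\n",
              x$macro_precision, x$macro_recall, x$macro_f1))
  invisible(x)
}

#' Cohort mean and spread of per-participant macro F1
#'
#' @param macro_f1 Numeric vector of per-participant macro F1 scores.
#' @return List with `mean` (arithmetic mean) and `sd` (population,
#'   n-normalised standard deviation).
#' @examples
#' aggregate_participants(c(0.892, 0.222, 0.333, 0.964,
#'                          0.317, 0.388, 0.263, 0.750))
#' @export
aggregate_participants <- function(macro_f1) {
  if (length(macro_f1) == 0) stop("empty score list")
  m <- mean(macro_f1)
  list(mean = m, sd = sqrt(mean((macro_f1 - m)^2)))
}

#' Family-by-window macro F1 table with row means
#'
#' Reshapes leave-one-out cross-validation results into the conventional
#' model x window-size summary table, appending the across-window mean of
#' each family's row.
#'
#' @param results Data frame with columns `family`, `window`, `macro_f1`
#'   (e.g. the `$pooled` element of a [loocv()] result, optionally filtered
#'   to one source subset / aggregation), or a `nirs_cv` object.
#' @param value Column to tabulate when `results` is a `nirs_cv` object
#'   (`"macro_f1_pooled"` or `"macro_f1_fold_mean"`).
#' @param subset Source subset to tabulate for a `nirs_cv` object.
#' @return Numeric matrix: one row per family, one column per window size,
#'   plus a `"Mean"` column.
#' @export
summarize_window_sweep <- function(results, value = "macro_f1_pooled",
                                   subset = "ALL") {
  if (inherits(results, "nirs_cv")) {
    df <- results$pooled[results$pooled$subset == subset, ]
    df <- data.frame(family = df$family, window = df$window,
                     macro_f1 = df[[value]])
  } else {
    df <- as.data.frame(results)
  }
  stopifnot(all(c("family", "window", "macro_f1") %in% names(df)))
  fams <- unique(df$family)
  wins <- sort(unique(df$window))
  tab <- matrix(NA_real_, length(fams), length(wins),
                dimnames = list(fams, as.character(wins)))
  for (i in seq_len(nrow(df))) {
    tab[df$family[i], as.character(df$window[i])] <- df$macro_f1[i]
  }
  if (anyNA(tab)) {
    stop("missing (family, window) cell(s) in sweep results")
  }
  cbind(tab, Mean = rowMeans(tab))
}
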