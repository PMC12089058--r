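#' Participant-level leave-one-out cross-validation
#'
#' Evaluates classifier families under participant-level LOO-CV with
#' leakage-proof preprocessing: in each fold one participant's complete
#' dataset is held out and the RLS short-channel coefficients and feature
#' scaler are fitted exclusively on the remaining (training) cohort.
#' Hyperparameters are chosen per fold by an inner grouped leave-one-out
#' cross-validation over the training participants (best mean inner macro
#' F1; ties resolve to the smallest grid value). The sweep repeats over
#' window sizes and source subsets, and results are aggregated both by
#' pooling confusion counts over folds (`macro_f1_pooled`) and by averaging
#' per-fold macro F1 (`macro_f1_fold_mean`).
#'
#' @param sessions List of `nirs_session` objects with distinct participant
#'   ids (>= 3 participants).
#' @param families Classifier families to evaluate, see [model_grid()].
#' @param window_frames Integer vector of window sizes (frames).
#' @param subsets Source subsets among `"ALL"`, `"LATERAL"`, `"MEDIAL"`.
#' @param stats Window statistics (offline default: all five).
#' @param k_best F-test feature selection size, `NULL` (offline default)
#'   for none.
#' @param lambda,delta RLS parameters.
#' @param filter_mode `"zero_phase"` (offline default) or `"causal"`.
#' @param permute_labels If `TRUE`, window labels are permuted within each
#'   participant (seeded) before training — the permutation null.
#' @param seed Seed for inner-CV/classifier randomness and permutations.
#' @return Object of class `nirs_cv`: list with `folds` (per subset x
#'   window x family x held-out participant: macro F1, chosen
#'   hyperparameter), `pooled` (per subset x window x family: pooled and
#'   fold-mean macro F1, fold SD), and `confusions`.
#' @export
loocv <- function(sessions, families = c("SVM_LINEAR", "RF"),
                  window_frames = 100, subsets = "ALL",
                  stats = FEATURE_STATS, k_best = NULL,
                  lambda = 0.999, delta = 100,
                  filter_mode = c("zero_phase", "causal"),
                  permute_labels = FALSE, seed = 1L) {
  filter_mode <- match.arg(filter_mode)
  stopifnot(length(sessions) >= 3)
  pids <- vapply(sessions, function(s) s$participant_id, character(1))
  if (anyDuplicated(pids)) {
    stop("leakage guard: participant id(s) ",
         paste(unique(pids[duplicated(pids)]), collapse = ", "),
         " appear in more than one session; each participant must be ",
         "either train or test, never both")
  }
  subsets <- toupper(subsets)
  zero_phase <- filter_mode == "zero_phase"
  folds <- list()
  confusions <- list()
  for (subset in subsets) {
    ## subset + bandpass are fold-independent; do them once
    prepped <- lapply(sessions, function(s) {
      if (s$mode == "RAW_INTENSITY") s <- mbll_convert(s)
      bandpass_session(source_subset(s, subset), zero_phase = zero_phase)
    })
    for (f in seq_along(prepped)) {
      test_pid <- pids[f]
      train_idx <- which(pids != test_pid)
      .assert_no_leakage(pids[train_idx], test_pid)
      ## preprocessing fitted on the training cohort only
      rls <- fit_rls_set(prepped[train_idx],
                         function(s) task_mask(s, unique(s$group)),
                         lambda = lambda, delta = delta)
      denoised <- lapply(prepped, apply_rls_set, filters = rls)
      for (W in window_frames) {
        tabs <- lapply(denoised, build_feature_table, window_frames = W,
                       stats = stats)
        if (permute_labels) {
          tabs <- lapply(seq_along(tabs), function(i) {
            permute_within(tabs[[i]], seed + 131 * i)
          })
        }
        train_tab <- bind_feature_tables(tabs[train_idx])
        test_tab <- tabs[[f]]
        .assert_no_leakage(train_tab$participant, test_pid)
        scaler <- fit_scaler(train_tab$X)
        Xtr <- apply_scaler(scaler, train_tab$X)
        Xte <- apply_scaler(scaler, test_tab$X)
        selector <- NULL
        if (!is.null(k_best)) {
          selector <- select_k_best(Xtr, train_tab$y, k_best)
          Xtr <- apply_selector(selector, Xtr)
          Xte <- apply_selector(selector, Xte)
        }
        for (family in families) {
          chosen <- pick_hyperparams(family, Xtr, train_tab$y,
                                     train_tab$participant, seed)
          model <- fit_classifier(Xtr, train_tab$y, family, chosen, seed)
          pred <- predict(model, Xte)
          cm <- confusion_counts(test_tab$y, pred)
          key <- paste(subset, W, family, sep = "|")
          confusions[[key]] <- if (is.null(confusions[[key]])) cm else
            confusions[[key]] + cm
          folds[[length(folds) + 1]] <- data.frame(
            subset = subset, window = W, family = family,
            participant = test_pid,
            macro_f1 = metrics_from_confusion(cm)$macro_f1,
            n_windows = sum(cm),
            params = paste(names(chosen), unlist(chosen), sep = "=",
                           collapse = ","),
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  folds <- do.call(rbind, folds)
  pooled <- do.call(rbind, lapply(names(confusions), function(key) {
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    sel <- folds$subset == parts[1] & folds$window == as.numeric(parts[2]) &
      folds$family == parts[3]
    data.frame(
      subset = parts[1], window = as.numeric(parts[2]), family = parts[3],
      macro_f1_pooled = metrics_from_confusion(confusions[[key]])$macro_f1,
      macro_f1_fold_mean = mean(folds$macro_f1[sel]),
      fold_sd = aggregate_participants(folds$macro_f1[sel])$sd,
      n_windows = sum(confusions[[key]]),
      stringsAsFactors = FALSE
    )
  }))
  structure(list(folds = folds, pooled = pooled, confusions = confusions,
                 permuted = permute_labels, seed = seed),
            class = "nirs_cv")
}

.assert_no_leakage <- function(train_pids, test_pid) {
  if (test_pid %in% train_pids) {
    stop("leakage guard: held-out participant ", test_pid,
         " present in training data")
  }
  invisible(TRUE)
}

permute_within <- function(tab, seed) {
  set.seed(seed)
  tab$y <- tab$y[sample(length(tab$y))]
  tab
}

bind_feature_tables <- function(tabs) {
  list(
    X = do.call(rbind, lapply(tabs, `[[`, "X")),
    y = factor(unlist(lapply(tabs, function(t) as.character(t$y))),
               levels = TASK_LEVELS),
    participant = unlist(lapply(tabs, `[[`, "participant")),
    group = unlist(lapply(tabs, `[[`, "group"))
  )
}

## Inner grouped LOO over training participants; mean macro F1 per grid
## point, first (smallest) value wins ties.
pick_hyperparams <- function(family, X, y, participant, seed) {
  grid <- model_grid(family)
  if (length(grid) == 1) return(grid[[1]])
  inner_pids <- unique(participant)
  scores <- vapply(grid, function(params) {
    f1s <- vapply(inner_pids, function(p) {
      tr <- participant != p
      if (nlevels(droplevels(y[tr])) < 2 ||
          nlevels(droplevels(y[!tr])) < 2) return(NA_real_)
      model <- fit_classifier(X[tr, , drop = FALSE], y[tr], family, params,
                              seed)
      pred <- predict(model, X[!tr, , drop = FALSE])
      metrics_from_confusion(confusion_counts(y[!tr], pred))$macro_f1
    }, numeric(1))
    mean(f1s, na.rm = TRUE)
  }, numeric(1))
  grid[[which.max(scores)]]
}

#' @export
print.nirs_cv <- function(x, ...) {
  cat("Participant-level LOO-CV",
      if (isTRUE(x$permuted)) "(label-permutation null)", "\n")
  df <- x$pooled
  df$macro_f1_pooled <- round(df$macro_f1_pooled, 3)
  df$macro_f1_fold_mean <- round(df$macro_f1_fold_mean, 3)
  df$fold_sd <- round(df$fold_sd, 3)
  print(df, row.names = FALSE)
  invisible(x)
}
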