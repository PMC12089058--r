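#' Restrict a session to one probe side
#'
#' Keeps only the long channels of the chosen side(s) together with the
#' matching short channel(s) (still needed as the superficial regressor).
#' `"ALL"` is the identity; the operation is idempotent.
#'
#' @param session A `nirs_session`.
#' @param subset `"ALL"`, `"LATERAL"` or `"MEDIAL"` (case-insensitive).
#' @return The filtered `nirs_session`.
#' @export
source_subset <- function(session, subset = c("ALL", "LATERAL", "MEDIAL")) {
  subset <- toupper(subset)
  subset <- match.arg(subset)
  if (subset == "ALL") return(session)
  side <- tolower(subset)
  if (!side %in% session$channel_info$side) stop("unknown side tag: ", subset)
  keep <- session$channel_info$side == side
  session$channels <- session$channels[, keep, drop = FALSE]
  session$channel_info <- session$channel_info[keep, , drop = FALSE]
  session
}

## Sample mask of task (non-rest) samples within the given trial groups.
task_mask <- function(session, groups) {
  session$labels %in% TASK_LEVELS & session$group %in% groups
}

#' Train a frozen fNIRS classification pipeline
#'
#' Fits the full processing chain on training data only, in order: source
#' subsetting, 0.1-0.4 Hz Butterworth bandpass, recursive-least-squares
#' short-channel regression (one filter per probe side and chromophore,
#' trained on the concatenated task samples of the training trial groups),
#' windowed feature extraction, z-score feature scaling, optional ANOVA
#' F-test feature selection, and a classifier. Every component is frozen in
#' the returned bundle, the unit shipped from training to online replay.
#'
#' @param sessions A `nirs_session` or list of them (`RAW_INTENSITY`
#'   sessions are first converted with [mbll_convert()]).
#' @param window_frames Analysis window length in frames (default 100,
#'   i.e. 17.24 s at 5.8 Hz).
#' @param stats Window statistics (online default `c("max", "mean")`).
#' @param k_best Number of features kept by F-test selection (default 10);
#'   `NULL` disables selection (the offline configuration).
#' @param family,params Classifier family and hyperparameters
#'   (default linear SVM, `C = 1`).
#' @param subset Source subset (`"ALL"`, `"LATERAL"`, `"MEDIAL"`).
#' @param train_groups Trial groups used for training; default `1:2` for a
#'   single session (the real-time protocol) and all groups for a cohort.
#' @param filter_mode `"causal"` (single-pass, real-time compatible; the
#'   default) or `"zero_phase"` (forward-backward, offline).
#' @param lambda,delta RLS forgetting factor and initialisation scale.
#' @param seed Seed for classifier training randomness.
#' @return Object of class `nirs_pipeline`.
#' @examples
#' s <- generate_session(session_config(seed = 7))
#' pl <- train_pipeline(s)
#' pl
#' @export
train_pipeline <- function(sessions, window_frames = 100,
                           stats = c("max", "mean"), k_best = 10,
                           family = "SVM_LINEAR", params = list(C = 1),
                           subset = "ALL", train_groups = NULL,
                           filter_mode = c("causal", "zero_phase"),
                           lambda = 0.999, delta = 100, seed = 1L) {
  filter_mode <- match.arg(filter_mode)
  if (inherits(sessions, "nirs_session")) sessions <- list(sessions)
  sessions <- lapply(sessions, function(s) {
    if (s$mode == "RAW_INTENSITY") mbll_convert(s) else s
  })
  if (is.null(train_groups)) {
    train_groups <- if (length(sessions) == 1) 1:2 else
      sort(unique(sessions[[1]]$group))
  }
  zero_phase <- filter_mode == "zero_phase"
  sessions <- lapply(sessions, function(s)
    source_subset(s, subset))
  sessions <- lapply(sessions, bandpass_session, zero_phase = zero_phase)
  rls <- fit_rls_set(sessions, function(s) task_mask(s, train_groups),
                     lambda = lambda, delta = delta)
  denoised <- lapply(sessions, apply_rls_set, filters = rls)
  ft <- build_feature_table(denoised, window_frames, stats,
                            groups = train_groups)
  if (nlevels(droplevels(ft$y)) < 2) {
    stop("training data must contain both task classes")
  }
  scaler <- fit_scaler(ft$X)
  Xs <- apply_scaler(scaler, ft$X)
  selector <- NULL
  if (!is.null(k_best)) {
    selector <- select_k_best(Xs, ft$y, k_best)
    Xs <- apply_selector(selector, Xs)
  }
  model <- fit_classifier(Xs, ft$y, family, params, seed)
  structure(
    list(window_frames = window_frames, stats = stats, subset = subset,
         filter_mode = filter_mode, train_groups = train_groups,
         rls = rls, scaler = scaler, selector = selector, model = model,
         levels = TASK_LEVELS, seed = as.integer(seed),
         n_train_windows = nrow(Xs)),
    class = "nirs_pipeline"
  )
}

## Frozen preprocessing of a session: subset, bandpass, RLS.
preprocess_session <- function(pipeline, session) {
  if (session$mode == "RAW_INTENSITY") session <- mbll_convert(session)
  session <- source_subset(session, pipeline$subset)
  session <- bandpass_session(session,
                              zero_phase = pipeline$filter_mode == "zero_phase")
  apply_rls_set(session, pipeline$rls)
}

## Frozen featurization: windows -> scaled (and selected) feature rows.
pipeline_features <- function(pipeline, sessions, groups = NULL,
                              window_frames = pipeline$window_frames) {
  ft <- build_feature_table(sessions, window_frames, pipeline$stats,
                            groups = groups)
  ft$X <- apply_scaler(pipeline$scaler, ft$X)
  if (!is.null(pipeline$selector)) ft$X <- apply_selector(pipeline$selector,
                                                          ft$X)
  ft
}

#' Replay a frozen pipeline over a test session
#'
#' Simulates the real-time experiment: walks the task blocks of the test
#' trial group(s) in contiguous windows of `stride_frames` samples, applies
#' the frozen preprocessing (bandpass, RLS coefficients, scaler, selected
#' features) and classifier to each window, and never updates any state.
#' Each block contributes `floor(n_block_samples / stride_frames)`
#' predictions.
#'
#' @param pipeline A fitted [train_pipeline()] bundle.
#' @param session Test `nirs_session`.
#' @param stride_frames Window/stride length (default: the pipeline's
#'   training window).
#' @param test_groups Trial groups to replay; default: the groups not used
#'   for training (the third group under the standard protocol).
#' @return Object of class `nirs_replay`: list with `predictions` (data
#'   frame: `group`, `block`, `window`, `task`, `pred`), `confusion`,
#'   `metrics`.
#' @export
online_replay <- function(pipeline, session,
                          stride_frames = pipeline$window_frames,
                          test_groups = NULL) {
  if (!inherits(pipeline, "nirs_pipeline")) stop("unfitted pipeline")
  if (is.null(test_groups)) {
    test_groups <- setdiff(unique(session$group), pipeline$train_groups)
    if (length(test_groups) == 0) test_groups <- unique(session$group)
  }
  proc <- preprocess_session(pipeline, session)
  long_ch <- proc$channel_info$channel[proc$channel_info$type == "long"]
  wins <- segment_windows(proc, stride_frames, groups = test_groups)
  if (nrow(wins) == 0) stop("no complete windows in the test groups")
  preds <- character(nrow(wins))
  for (i in seq_len(nrow(wins))) {
    w <- proc$channels[wins$start[i]:wins$end[i], long_ch, drop = FALSE]
    x <- extract_features(w, pipeline$stats, proc$fs_hz)
    x <- apply_scaler(pipeline$scaler, matrix(x, 1,
                                              dimnames = list(NULL, names(x))))
    if (!is.null(pipeline$selector)) x <- apply_selector(pipeline$selector, x)
    preds[i] <- as.character(predict(pipeline$model, x))
  }
  predictions <- data.frame(
    group = wins$group, block = wins$block,
    window = stats::ave(wins$block, wins$block, FUN = seq_along),
    task = wins$task, pred = preds, stringsAsFactors = FALSE
  )
  cm <- confusion_counts(predictions$task, predictions$pred, pipeline$levels)
  structure(
    list(predictions = predictions, confusion = cm,
         metrics = metrics_from_confusion(cm)),
    class = "nirs_replay"
  )
}

#' @export
print.nirs_replay <- function(x, ...) {
  cat("Online replay:", nrow(x$predictions), "windows\n")
  print(x$metrics)
  invisible(x)
}

#' @export
#' @rdname online_replay
#' @param object,newdata,... Pipeline, test session and arguments passed on
#'   to `online_replay()`.
predict.nirs_pipeline <- function(object, newdata, ...) {
  online_replay(object, newdata, ...)
}

#' @export
print.nirs_pipeline <- function(x, ...) {
  cat("fNIRS classification pipeline\n")
  cat("  subset:", x$subset, " filter:", x$filter_mode,
      " window:", x$window_frames, "frames\n")
  cat("  stats:", paste(x$stats, collapse = ", "),
      if (!is.null(x$selector)) paste0(" -> top ", x$selector$k,
                                       " by F-test") else "", "\n")
  cat("  classifier:", x$model$family, "| trained on", x$n_train_windows,
      "windows (groups", paste(x$train_groups, collapse = ","), ")\n")
  invisible(x)
}

#' @export
summary.nirs_pipeline <- function(object, ...) {
  print(object)
  cat("\nRLS filters:\n")
  for (nm in names(object$rls)) {
    w <- object$rls[[nm]]$w
    cat("  ", nm, ": slopes",
        paste(sprintf("%.3f", w[1, ]), collapse = ", "), "\n")
  }
  invisible(object)
}

#' @export
#' @rdname train_pipeline
#' @param object A fitted pipeline.
#' @param ... Unused.
coef.nirs_pipeline <- function(object, ...) {
  lapply(object$rls, function(f) f$w)
}

#' Serialise / restore a trained pipeline
#'
#' The preprocessing state (RLS coefficients, scaler parameters, selected
#' feature indices, window specification) is written as JSON; the fitted
#' classifier object is stored alongside it in RDS form. Reloading
#' reproduces predictions exactly.
#'
#' @param pipeline A fitted `nirs_pipeline`.
#' @param dir Directory to write the bundle into (created if needed).
#' @return `write_pipeline` returns `dir` invisibly; `read_pipeline` the
#'   restored `nirs_pipeline`.
#' @export
write_pipeline <- function(pipeline, dir) {
  stopifnot(inherits(pipeline, "nirs_pipeline"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(
    window_frames = pipeline$window_frames, stats = pipeline$stats,
    subset = pipeline$subset, filter_mode = pipeline$filter_mode,
    train_groups = pipeline$train_groups, levels = pipeline$levels,
    seed = pipeline$seed, n_train_windows = pipeline$n_train_windows,
    rls = lapply(pipeline$rls, function(f) {
      list(w = f$w, P = f$P, lambda = f$lambda, delta = f$delta,
           intercept = f$intercept, n_train = f$n_train,
           targets = f$targets)
    }),
    scaler = list(mean = pipeline$scaler$mean, sd = pipeline$scaler$sd,
                  constant = pipeline$scaler$constant),
    selector = if (!is.null(pipeline$selector)) {
      list(k = pipeline$selector$k, indices = pipeline$selector$indices,
           f_stat = pipeline$selector$f_stat)
    }
  )
  jsonlite::write_json(meta, file.path(dir, "pipeline.json"),
                       auto_unbox = TRUE, digits = NA)
  saveRDS(pipeline$model, file.path(dir, "classifier.rds"))
  invisible(dir)
}

#' @rdname write_pipeline
#' @export
read_pipeline <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "pipeline.json"),
                              simplifyVector = TRUE)
  rls <- lapply(meta$rls, function(f) {
    w <- as.matrix(f$w)
    colnames(w) <- f$targets
    structure(list(w = w, P = as.matrix(f$P), lambda = f$lambda,
                   delta = f$delta, intercept = f$intercept,
                   n_train = f$n_train, targets = f$targets),
              class = "nirs_rls")
  })
  scaler <- structure(list(mean = unlist(meta$scaler$mean),
                           sd = unlist(meta$scaler$sd),
                           constant = unlist(meta$scaler$constant)),
                      class = "nirs_scaler")
  selector <- NULL
  if (!is.null(meta$selector) && length(meta$selector) > 0) {
    selector <- structure(list(k = meta$selector$k,
                               indices = meta$selector$indices,
                               f_stat = meta$selector$f_stat),
                          class = "nirs_selector")
  }
  structure(
    list(window_frames = meta$window_frames, stats = meta$stats,
         subset = meta$subset, filter_mode = meta$filter_mode,
         train_groups = meta$train_groups, rls = rls, scaler = scaler,
         selector = selector,
         model = readRDS(file.path(dir, "classifier.rds")),
         levels = meta$levels, seed = meta$seed,
         n_train_windows = meta$n_train_windows),
    class = "nirs_pipeline"
  )
}
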