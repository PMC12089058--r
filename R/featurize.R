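FEATURE_STATS <- c("max", "mean", "sd", "skew", "slope")

#' Segment a session into fixed-length task windows
#'
#' Walks each task block (rest blocks are never windowed: the classifier is
#' binary) and cuts consecutive non-overlapping windows of exactly
#' `window_frames` samples; a partial trailing window is dropped. Every
#' window therefore contains samples of a single task, and its label is the
#' block's task.
#'
#' @param session A `nirs_session`.
#' @param window_frames Window length in frames (samples).
#' @param stride Step between window starts (default `window_frames`:
#'   non-overlapping).
#' @param groups Optional integer vector restricting to these trial groups.
#' @return Data frame with one row per window: `start`, `end`, `task`,
#'   `group`, `block`.
#' @examples
#' s <- generate_session(session_config(seed = 1))
#' head(segment_windows(s, 100))
#' @export
segment_windows <- function(session, window_frames, stride = window_frames,
                            groups = NULL) {
  stopifnot(inherits(session, "nirs_session"),
            window_frames > 0, stride > 0)
  blocks <- unique(session$block[session$labels %in% TASK_LEVELS])
  if (!is.null(groups)) {
    blocks <- blocks[unique_block_group(session, blocks) %in% groups]
  }
  all_blocks <- unique(session$block[session$labels %in% TASK_LEVELS])
  max_len <- max(tabulate(match(session$block, all_blocks)))
  if (window_frames > max_len) {
    stop("window_frames (", window_frames,
         ") is longer than every task block (max ", max_len, " frames)")
  }
  out <- list()
  for (b in blocks) {
    idx <- which(session$block == b)
    if (idx[length(idx)] - idx[1] + 1 < window_frames) next
    starts <- seq(idx[1], idx[length(idx)] - window_frames + 1, by = stride)
    for (st in starts) {
      out[[length(out) + 1]] <- data.frame(
        start = st, end = st + window_frames - 1,
        task = session$labels[st], group = session$group[st], block = b,
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(out) == 0) {
    return(data.frame(start = integer(0), end = integer(0),
                      task = character(0), group = integer(0),
                      block = integer(0)))
  }
  do.call(rbind, out)
}

unique_block_group <- function(session, blocks) {
  vapply(blocks, function(b) session$group[match(b, session$block)],
         integer(1))
}

#' Per-channel window statistics
#'
#' Computes the requested statistics for each column of a window. `max` and
#' `mean` are the online feature set; `sd`, `skew` (Fisher skewness, defined
#' as 0 for a zero-variance window) and `slope` (ordinary least-squares slope
#' of value against time in seconds, so values are sampling-rate invariant)
#' extend it for offline analysis.
#'
#' @param window n x c numeric matrix (one column per channel).
#' @param stats Character subset of `c("max", "mean", "sd", "skew", "slope")`.
#' @param fs_hz Sampling rate, needed for `slope`.
#' @return Named numeric vector of length `c * length(stats)`, names
#'   `"<channel>_<stat>"`.
#' @export
extract_features <- function(window, stats = c("max", "mean"), fs_hz = 5.8) {
  window <- as.matrix(window)
  if (nrow(window) == 0) stop("empty window")
  stats <- match.arg(stats, FEATURE_STATS, several.ok = TRUE)
  n <- nrow(window)
  tsec <- (seq_len(n) - 1) / fs_hz
  tc <- tsec - mean(tsec)
  vals <- lapply(stats, function(st) {
    switch(st,
      max = apply(window, 2, max),
      mean = colMeans(window),
      sd = apply(window, 2, stats::sd),
      skew = apply(window, 2, function(v) {
        m2 <- mean((v - mean(v))^2)
        if (m2 == 0) return(0)
        mean((v - mean(v))^3) / m2^1.5
      }),
      slope = if (n < 2) stop("slope needs >= 2 samples") else
        as.numeric(crossprod(tc, sweep(window, 2, colMeans(window))) /
                     sum(tc^2))
    )
  })
  out <- unlist(lapply(seq_along(stats), function(i) {
    v <- vals[[i]]
    names(v) <- paste0(colnames(window), "_", stats[i])
    v
  }))
  out
}

#' Build a windows-by-features table from sessions
#'
#' Segments the long channels of each session into task windows and extracts
#' per-channel statistics, keeping the task label, participant id, and trial
#' group of every window.
#'
#' @param sessions A `nirs_session` or list of them (already preprocessed:
#'   bandpassed and short-channel denoised as appropriate).
#' @param window_frames Window length in frames.
#' @param stats Statistic set, see [extract_features()].
#' @param groups Optional trial-group restriction.
#' @return Object of class `nirs_features`: list with `X` (matrix), `y`
#'   (factor with levels visualization/workload), `participant`, `group`,
#'   `block`, `feature_names`.
#' @export
build_feature_table <- function(sessions, window_frames,
                                stats = c("max", "mean"), groups = NULL) {
  if (inherits(sessions, "nirs_session")) sessions <- list(sessions)
  rows <- list()
  meta <- list()
  for (s in sessions) {
    stopifnot(s$mode == "DELTA_HB")
    long_ch <- s$channel_info$channel[s$channel_info$type == "long"]
    wins <- segment_windows(s, window_frames, groups = groups)
    for (i in seq_len(nrow(wins))) {
      w <- s$channels[wins$start[i]:wins$end[i], long_ch, drop = FALSE]
      rows[[length(rows) + 1]] <- extract_features(w, stats, s$fs_hz)
      meta[[length(meta) + 1]] <- data.frame(
        task = wins$task[i], participant = s$participant_id,
        group = wins$group[i], block = wins$block[i],
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0) stop("no complete windows")
  X <- do.call(rbind, rows)
  md <- do.call(rbind, meta)
  structure(
    list(X = X, y = factor(md$task, levels = TASK_LEVELS),
         participant = md$participant, group = md$group, block = md$block,
         feature_names = colnames(X)),
    class = "nirs_features"
  )
}

#' Standard (z-score) feature scaler
#'
#' `fit_scaler` learns per-feature mean and standard deviation on training
#' rows; `apply_scaler` transforms any rows with the frozen parameters.
#' A constant feature (sd below tolerance) is flagged and passed through
#' centred only. Note the transform is deliberately not idempotent: applying
#' frozen parameters twice rescales again.
#'
#' @param X Numeric matrix of training rows (windows x features).
#' @return `fit_scaler`: object of class `nirs_scaler` with `mean`, `sd`,
#'   `constant`; `apply_scaler`: the transformed matrix.
#' @export
fit_scaler <- function(X) {
  m <- colMeans(X)
  s <- apply(X, 2, stats::sd)
  constant <- !is.finite(s) | s < 1e-12
  s[constant] <- 1
  structure(list(mean = m, sd = s, constant = constant),
            class = "nirs_scaler")
}

#' @rdname fit_scaler
#' @param scaler A fitted `nirs_scaler`.
#' @export
apply_scaler <- function(scaler, X) {
  stopifnot(inherits(scaler, "nirs_scaler"), ncol(X) == length(scaler$mean))
  sweep(sweep(X, 2, scaler$mean), 2, scaler$sd, "/")
}

#' Select the K best features by one-way ANOVA F statistic
#'
#' Scores each feature with the one-way ANOVA F statistic of feature value
#' against class label and retains the `k` largest; ties are broken in
#' favour of the lower feature index.
#'
#' @param X Feature matrix (training rows).
#' @param y Class labels (factor or character), at least two classes.
#' @param k Number of features to keep (default 10); capped at `ncol(X)`.
#' @return Object of class `nirs_selector`: list with `k`, `indices`
#'   (selected columns, ascending), `f_stat` (per-feature F statistics).
#' @export
select_k_best <- function(X, y, k = 10) {
  y <- factor(y)
  if (nlevels(droplevels(y)) < 2) stop("need at least 2 classes")
  n <- nrow(X)
  g <- as.integer(droplevels(y))
  ng <- tabulate(g)
  kg <- length(ng)
  grand <- colMeans(X)
  ssb <- rep(0, ncol(X))
  ssw <- rep(0, ncol(X))
  for (j in seq_len(kg)) {
    Xg <- X[g == j, , drop = FALSE]
    mg <- colMeans(Xg)
    ssb <- ssb + ng[j] * (mg - grand)^2
    ssw <- ssw + colSums(sweep(Xg, 2, mg)^2)
  }
  f <- ifelse(ssw > 0, (ssb / (kg - 1)) / (ssw / (n - kg)), Inf)
  keep <- min(k, ncol(X))
  ord <- order(-f, seq_along(f))
  idx <- sort(ord[seq_len(keep)])
  structure(list(k = k, indices = idx, f_stat = f),
            class = "nirs_selector")
}

#' @rdname select_k_best
#' @param selector A fitted `nirs_selector`.
#' @export
apply_selector <- function(selector, X) {
  stopifnot(inherits(selector, "nirs_selector"))
  X[, selector$indices, drop = FALSE]
}
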