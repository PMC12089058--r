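#' Configuration for one synthetic fNIRS session
#'
#' Collects the generative parameters of a synthetic session: sampling rate,
#' task-evoked effect amplitudes per probe side and task, the superficial
#' (systemic) noise model shared between short and long channels, and the
#' participant-level variability. Amplitudes are in micromolar (µM) change in
#' chromophore concentration.
#'
#' The default effect structure is a double dissociation: the visualization
#' task drives the medial channels more strongly and the workload task the
#' lateral channels, emulating tasks that preferentially engage default-mode
#' versus dorsolateral-prefrontal territory under a single frontal probe.
#'
#' @param participant_id Character id of the simulated participant.
#' @param seed Integer RNG seed; the generator is fully deterministic given
#'   the configuration (which includes this seed).
#' @param fs_hz Sampling rate; fixed-design default 5.8 Hz.
#' @param task_block_duration_s Task block length in seconds (default 60).
#' @param effect Named list `lateral`/`medial`, each a named numeric vector
#'   with the HbO response amplitude (µM) for `visualization` and `workload`.
#' @param hbr_ratio Scale of the HbR task response relative to HbO; negative
#'   for the typical inverted, smaller HbR response.
#' @param noise List with `cardiac`, `respiration`, `mayer` (each
#'   `c(amp = , freq = )`, amplitude in µM, frequency in Hz), `drift_sd`
#'   (µM, slow random-walk drift), and `white_sd` (µM per sample).
#' @param superficial_gain Coupling of the shared superficial component into
#'   each long channel (the short channel observes it with gain 1).
#' @param between_participant_sd SD of the log-normal perturbation applied
#'   once per participant to effect amplitudes and noise SDs.
#' @param mode `"DELTA_HB"` (chromophore concentration channels) or
#'   `"RAW_INTENSITY"` (dual-wavelength intensities forward-modelled through
#'   the Modified Beer-Lambert Law).
#' @return A list of class `nirs_config`.
#' @export
session_config <- function(participant_id = "P1",
                           seed = 1L,
                           fs_hz = 5.8,
                           task_block_duration_s = 60,
                           effect = list(
                             lateral = c(visualization = 0.1, workload = 0.4),
                             medial = c(visualization = 0.4, workload = 0.1)
                           ),
                           hbr_ratio = -0.3,
                           noise = list(
                             cardiac = c(amp = 0.08, freq = 1.1),
                             respiration = c(amp = 0.10, freq = 0.25),
                             mayer = c(amp = 0.15, freq = 0.10),
                             drift_sd = 0.10,
                             white_sd = 0.02
                           ),
                           superficial_gain = 0.8,
                           between_participant_sd = 0.2,
                           mode = c("DELTA_HB", "RAW_INTENSITY")) {
  mode <- match.arg(mode)
  if (is.null(seed) || is.na(seed)) stop("seed must be set")
  stopifnot(fs_hz > 0, task_block_duration_s > 0)
  amps <- c(noise$cardiac["amp"], noise$respiration["amp"],
            noise$mayer["amp"], noise$drift_sd, noise$white_sd,
            unlist(effect, use.names = FALSE))
  if (any(amps < 0)) stop("all amplitudes must be >= 0")
  structure(
    list(participant_id = participant_id, seed = as.integer(seed),
         fs_hz = fs_hz, task_block_duration_s = task_block_duration_s,
         effect = effect, hbr_ratio = hbr_ratio, noise = noise,
         superficial_gain = superficial_gain,
         between_participant_sd = between_participant_sd, mode = mode),
    class = "nirs_config"
  )
}

#' Canonical double-gamma haemodynamic response function
#'
#' Difference of two gamma densities (response peak 6 s, undershoot peak
#' 16 s, undershoot ratio 1/6), normalised so that convolution with a long
#' boxcar plateaus at 1: a task amplitude of `a` µM produces a sustained
#' response of `a` µM.
#'
#' @param t Time points in seconds (t >= 0).
#' @param fs_hz Sampling rate used for the plateau normalisation.
#' @return Numeric vector of kernel weights at `t`.
#' @export
hrf_double_gamma <- function(t, fs_hz) {
  h <- stats::dgamma(t, shape = 7, rate = 1) -
    stats::dgamma(t, shape = 17, rate = 1) / 6
  h / (sum(h) / fs_hz) / fs_hz
}

## Expand a protocol into per-sample label/group/block vectors.
expand_protocol <- function(protocol, fs_hz) {
  ns <- n_samples_for(protocol$duration_s, fs_hz)
  list(
    label = rep(protocol$task, ns),
    group = rep(protocol$group, ns),
    block = rep(protocol$block, ns),
    n = sum(ns)
  )
}

#' Generate one synthetic fNIRS session
#'
#' Simulates a multichannel session under a block protocol. Each long channel
#' is the sum of a task-locked response (double-gamma HRF convolved with that
#' task's boxcar, scaled by the side x task x chromophore effect), a shared
#' superficial component (cardiac, respiratory and Mayer-wave sinusoids with
#' participant-random phases plus a slow drift) coupled in with
#' `superficial_gain`, and white noise. Each short channel observes the same
#' superficial component (gain 1) plus white noise and carries no task-locked
#' term. One superficial process is generated per (side, chromophore).
#'
#' In `RAW_INTENSITY` mode the ΔHb channels are forward-modelled to
#' dual-wavelength optical densities through the Modified Beer-Lambert Law
#' and exponentiated around a unit baseline intensity; the generating ΔHb
#' (referenced to the baseline window) is attached as `truth`.
#'
#' @param config A [session_config()] object.
#' @param layout A [make_default_layout()] layout.
#' @param protocol A [make_protocol()] protocol; defaults to one built from
#'   `config$task_block_duration_s`.
#' @param baseline_s Length (s) of the session-initial baseline window used
#'   to reference intensities in `RAW_INTENSITY` mode.
#' @return An object of class `nirs_session`: list with `channels`
#'   (n_samples x n_channels matrix), `channel_info`, `fs_hz`, `labels`,
#'   `group`, `block`, `participant_id`, `mode` and (raw mode only) `truth`.
#' @examples
#' s <- generate_session(session_config(seed = 42))
#' dim(s$channels)
#' @export
generate_session <- function(config,
                             layout = make_default_layout(),
                             protocol = make_protocol(config$task_block_duration_s),
                             baseline_s = 10) {
  stopifnot(inherits(config, "nirs_config"))
  if (!config$mode %in% c("DELTA_HB", "RAW_INTENSITY")) {
    stop("unknown mode: ", config$mode)
  }
  fs <- config$fs_hz
  set.seed(config$seed)
  ex <- expand_protocol(protocol, fs)
  n <- ex$n
  tvec <- (seq_len(n) - 1) / fs

  ## once-per-participant log-normal perturbation of amplitudes
  bsd <- config$between_participant_sd
  perturb <- function(x) x * exp(stats::rnorm(length(x), 0, bsd))
  effect <- lapply(config$effect, perturb)
  noise <- config$noise
  noise$cardiac["amp"] <- perturb(noise$cardiac["amp"])
  noise$respiration["amp"] <- perturb(noise$respiration["amp"])
  noise$mayer["amp"] <- perturb(noise$mayer["amp"])
  noise$white_sd <- perturb(noise$white_sd)

  ## task-locked responses: HRF (x) task boxcar, unit plateau
  kern_t <- seq(0, 32, by = 1 / fs)
  h <- hrf_double_gamma(kern_t, fs)
  conv_boxcar <- function(box) {
    y <- stats::convolve(box, rev(h), type = "open")[seq_len(n)]
    y
  }
  resp <- sapply(TASK_LEVELS, function(task) {
    conv_boxcar(as.numeric(ex$label == task))
  })

  ## shared superficial process per (side, chromophore); HbR systemic
  ## oscillations smaller, with their own phases
  superficial <- function(chrom_scale) {
    comps <- rbind(noise$cardiac, noise$respiration, noise$mayer)
    s <- rep(0, n)
    for (i in seq_len(nrow(comps))) {
      phase <- stats::runif(1, 0, 2 * pi)
      s <- s + chrom_scale * comps[i, "amp"] *
        sin(2 * pi * comps[i, "freq"] * tvec + phase)
    }
    s + chrom_scale * noise$drift_sd * cumsum(stats::rnorm(n)) / sqrt(n)
  }
  sup <- list()
  for (side in SIDE_LEVELS) {
    sup[[side]] <- list(HbO = superficial(1), HbR = superficial(0.3))
  }

  pos <- layout$positions
  chroms <- c("HbO", "HbR")
  n_ch <- nrow(pos) * 2
  channels <- matrix(0, n, n_ch)
  info <- data.frame(
    channel = character(n_ch), position = integer(n_ch),
    side = character(n_ch), type = character(n_ch),
    chromophore = character(n_ch), distance_cm = numeric(n_ch),
    stringsAsFactors = FALSE
  )
  wsd <- noise$white_sd
  ci <- 0
  for (p in seq_len(nrow(pos))) {
    for (chrom in chroms) {
      ci <- ci + 1
      side <- pos$side[p]
      chrom_scale <- if (chrom == "HbO") 1 else config$hbr_ratio
      y <- sup[[side]][[chrom]] * if (pos$type[p] == "long")
        config$superficial_gain else 1
      if (pos$type[p] == "long") {
        task_part <- resp %*% effect[[side]][colnames(resp)]
        y <- y + chrom_scale * as.numeric(task_part)
      }
      y <- y + stats::rnorm(n, 0, wsd)
      channels[, ci] <- y
      info[ci, ] <- list(
        paste0("P", pos$position[p], "_", side, "_", chrom),
        pos$position[p], side, pos$type[p], chrom, pos$distance_cm[p]
      )
    }
  }
  colnames(channels) <- info$channel

  session <- structure(
    list(channels = channels, channel_info = info, fs_hz = fs,
         labels = ex$label, group = ex$group, block = ex$block,
         participant_id = config$participant_id, mode = "DELTA_HB",
         config = config, layout = layout),
    class = "nirs_session"
  )
  if (config$mode == "RAW_INTENSITY") {
    session <- delta_hb_to_intensity(session, baseline_s = baseline_s)
  }
  session
}

## Forward MBLL: ΔHb (µM) -> dual-wavelength intensities around unit
## baseline. ΔHb is first referenced to the baseline window so that the
## inverse conversion recovers it exactly.
delta_hb_to_intensity <- function(session, baseline_s = 10, dpf = 6,
                                  extinction = extinction_coefficients()) {
  stopifnot(session$mode == "DELTA_HB")
  n <- nrow(session$channels)
  nb <- max(2L, n_samples_for(baseline_s, session$fs_hz))
  base_idx <- seq_len(min(nb, n))
  info <- session$channel_info
  wl <- c(690, 830)
  out <- matrix(0, n, nrow(info))
  out_info <- info
  truth <- session$channels
  for (p in unique(info$position)) {
    rows <- which(info$position == p)
    hbo_col <- rows[info$chromophore[rows] == "HbO"]
    hbr_col <- rows[info$chromophore[rows] == "HbR"]
    d <- info$distance_cm[rows[1]]
    conc <- cbind(session$channels[, hbo_col], session$channels[, hbr_col])
    conc <- sweep(conc, 2, colMeans(conc[base_idx, , drop = FALSE]))
    truth[, hbo_col] <- conc[, 1]
    truth[, hbr_col] <- conc[, 2]
    ## µM -> mM, then ΔOD = E %*% c * d * DPF
    od <- (conc / 1000) %*% t(extinction) * d * dpf
    for (k in 1:2) {
      col <- rows[k]
      out[, col] <- 10^(-od[, k])
      out_info$channel[col] <- paste0("P", p, "_", info$side[rows[1]], "_",
                                      wl[k])
      out_info$chromophore[col] <- as.character(wl[k])
    }
  }
  colnames(out) <- out_info$channel
  colnames(truth) <- info$channel
  session$channels <- out
  session$channel_info <- out_info
  session$mode <- "RAW_INTENSITY"
  session$truth <- truth
  session$baseline_samples <- base_idx
  session
}

#' Generate a cohort of synthetic participants
#'
#' Participant-level seeds are derived from the master seed by a counter
#' scheme, so adding a participant never perturbs the others' data.
#'
#' @param n_participants Number of participants.
#' @param seed Master seed.
#' @param config_args Named list of overrides passed to [session_config()].
#' @param ... Passed to [generate_session()].
#' @return List of `nirs_session` objects.
#' @export
generate_cohort <- function(n_participants = 8, seed = 1L,
                            config_args = list(), ...) {
  lapply(seq_len(n_participants), function(i) {
    args <- config_args
    args$participant_id <- paste0("P", i)
    args$seed <- as.integer((as.numeric(seed) * 10007 + 7919 * i) %%
                              2147483647)
    generate_session(do.call(session_config, args), ...)
  })
}

#' @export
print.nirs_session <- function(x, ...) {
  cat("fNIRS session", x$participant_id, "(", x$mode, ")\n")
  cat("  ", nrow(x$channels), "samples x", ncol(x$channels), "channels at",
      x$fs_hz, "Hz\n")
  cat("  labels:", paste(sprintf("%s=%d", names(table(x$labels)),
                                 as.integer(table(x$labels))),
                         collapse = ", "), "\n")
  invisible(x)
}

#' Write / read a session as CSV
#'
#' One file per session: `#`-prefixed metadata header lines (sampling rate,
#' participant, mode, channel metadata) followed by a CSV table with
#' `time_s`, one column per channel, `label`, `group`, `block`.
#'
#' @param session A `nirs_session`.
#' @param path Output file path.
#' @return `write_session` returns `path` invisibly; `read_session` returns
#'   the reconstructed `nirs_session`.
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "nirs_session"))
  info <- session$channel_info
  meta <- c(
    paste0("# fs_hz: ", format(session$fs_hz, digits = 15)),
    paste0("# participant_id: ", session$participant_id),
    paste0("# mode: ", session$mode),
    paste0("# channel_meta: ",
           paste(apply(info, 1, function(r)
             paste(trimws(r), collapse = "|")), collapse = ";"))
  )
  df <- data.frame(time_s = (seq_len(nrow(session$channels)) - 1) /
                     session$fs_hz,
                   session$channels, check.names = FALSE)
  df$label <- session$labels
  df$group <- session$group
  df$block <- session$block
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta, con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_session
#' @export
read_session <- function(path) {
  lines <- readLines(path, n = 20)
  meta_lines <- grep("^# ", lines, value = TRUE)
  get_meta <- function(key) {
    ln <- grep(paste0("^# ", key, ": "), meta_lines, value = TRUE)
    if (length(ln) != 1) stop("malformed session file: missing ", key)
    sub(paste0("^# ", key, ": "), "", ln)
  }
  fs <- as.numeric(get_meta("fs_hz"))
  pid <- get_meta("participant_id")
  mode <- get_meta("mode")
  meta_rows <- strsplit(strsplit(get_meta("channel_meta"), ";")[[1]], "\\|")
  info <- do.call(rbind, lapply(meta_rows, function(r) {
    data.frame(channel = r[1], position = as.integer(r[2]), side = r[3],
               type = r[4], chromophore = r[5], distance_cm = as.numeric(r[6]),
               stringsAsFactors = FALSE)
  }))
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  required <- c("time_s", info$channel, "label", "group", "block")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("malformed session file: missing column(s) ",
         paste(missing, collapse = ", "))
  }
  channels <- as.matrix(df[, info$channel, drop = FALSE])
  structure(
    list(channels = channels, channel_info = info, fs_hz = fs,
         labels = df$label, group = df$group, block = df$block,
         participant_id = pid, mode = mode),
    class = "nirs_session"
  )
}
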