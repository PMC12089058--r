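# Shared synthetic fixtures, built in code at test time.

quick_session <- function(seed = 1, ...) {
  generate_session(session_config(seed = seed, ...))
}

# Noise-free deterministic config: no white noise, no participant
# variability; superficial process fully shared (gain 1 unless overridden).
clean_config <- function(seed = 1, superficial_gain = 1, ...) {
  session_config(
    seed = seed,
    noise = list(cardiac = c(amp = 0.08, freq = 1.1),
                 respiration = c(amp = 0.10, freq = 0.25),
                 mayer = c(amp = 0.15, freq = 0.10),
                 drift_sd = 0.10, white_sd = 0),
    superficial_gain = superficial_gain,
    between_participant_sd = 0,
    ...
  )
}

# Independent HRF-convolved boxcar oracle: explicit causal convolution sum,
# independent of the generator's FFT-based path.
oracle_task_response <- function(session, task) {
  fs <- session$fs_hz
  h <- hrf_double_gamma(seq(0, 32, by = 1 / fs), fs)
  box <- as.numeric(session$labels == task)
  L <- length(h)
  y <- stats::filter(c(rep(0, L - 1), box), h, sides = 1)
  as.numeric(y)[-seq_len(L - 1)]
}
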