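test_that("generation is deterministic given config and seed", {
  a <- quick_session(seed = 11)
  b <- quick_session(seed = 11)
  expect_identical(a$channels, b$channels)
  expect_identical(a$labels, b$labels)
  c <- quick_session(seed = 12)
  expect_false(identical(a$channels, c$channels))
})

test_that("noise-free session decomposes as task response + shared superficial", {
  s <- generate_session(clean_config(seed = 5))
  info <- s$channel_info
  # long minus short (gain 1, white sd 0) leaves the pure task response
  resp_vis <- oracle_task_response(s, "visualization")
  resp_work <- oracle_task_response(s, "workload")
  for (side in c("lateral", "medial")) {
    long1 <- s$channels[, info$channel[info$side == side & info$type == "long" &
                                         info$chromophore == "HbO"][1]]
    short <- s$channels[, info$channel[info$side == side & info$type == "short" &
                                         info$chromophore == "HbO"]]
    eff <- s$config$effect[[side]]
    expected <- eff["visualization"] * resp_vis + eff["workload"] * resp_work
    expect_lt(max(abs((long1 - short) - expected)), 1e-8)
  }
})

test_that("short channels carry no task-locked component", {
  s <- generate_session(clean_config(seed = 6))
  resp <- oracle_task_response(s, "visualization") +
    oracle_task_response(s, "workload")
  info <- s$channel_info
  shorts <- info$channel[info$type == "short"]
  for (ch in shorts) {
    expect_lt(abs(cor(s$channels[, ch], resp)), 0.1)
  }
  # while long channels do correlate with it
  long_hbo <- info$channel[info$type == "long" & info$chromophore == "HbO"]
  expect_gt(max(abs(cor(s$channels[, long_hbo], resp))), 0.3)
})

test_that("zero effect amplitudes remove the task-locked component", {
  cfg <- session_config(
    seed = 7,
    effect = list(lateral = c(visualization = 0, workload = 0),
                  medial = c(visualization = 0, workload = 0)),
    noise = list(cardiac = c(amp = 0.0, freq = 1.1),
                 respiration = c(amp = 0.0, freq = 0.25),
                 mayer = c(amp = 0.0, freq = 0.10),
                 drift_sd = 0, white_sd = 0.01),
    superficial_gain = 0, between_participant_sd = 0
  )
  s <- generate_session(cfg)
  resp <- oracle_task_response(s, "visualization")
  long_hbo <- s$channel_info$channel[s$channel_info$type == "long" &
                                       s$channel_info$chromophore == "HbO"]
  # nothing but white noise left: no correlation with the task regressor
  expect_lt(max(abs(cor(s$channels[, long_hbo], resp))), 0.05)
})

test_that("superficial components peak at their configured frequencies", {
  s <- generate_session(clean_config(seed = 8))
  short <- s$channels[, s$channel_info$channel[s$channel_info$type == "short" &
                                                 s$channel_info$chromophore ==
                                                   "HbO"][1]]
  pg <- stats::spec.pgram(stats::ts(short, frequency = s$fs_hz),
                          plot = FALSE, taper = 0, detrend = TRUE)
  peak_near <- function(f0, tol = 0.03) {
    band <- pg$freq > f0 - tol & pg$freq < f0 + tol
    max(pg$spec[band])
  }
  background <- stats::median(pg$spec)
  # periodogram oracle: strong power at cardiac, respiratory, Mayer rates
  for (f0 in c(1.1, 0.25, 0.10)) {
    expect_gt(peak_near(f0), 50 * background)
  }
})

test_that("sessions round-trip through CSV", {
  s <- quick_session(seed = 9)
  path <- tempfile(fileext = ".csv")
  write_session(s, path)
  r <- read_session(path)
  expect_equal(r$channels, s$channels, tolerance = 1e-12)
  expect_identical(r$labels, s$labels)
  expect_identical(r$group, s$group)
  expect_equal(r$fs_hz, s$fs_hz)
  expect_identical(r$participant_id, s$participant_id)
  expect_identical(r$mode, s$mode)
  expect_identical(r$channel_info$channel, s$channel_info$channel)
  unlink(path)
})

test_that("malformed session files are rejected", {
  s <- quick_session(seed = 10)
  path <- tempfile(fileext = ".csv")
  write_session(s, path)
  lines <- readLines(path)
  header_idx <- grep("time_s", lines)[1]
  cols <- strsplit(lines[header_idx], ",")[[1]]
  keep <- !grepl("^\"?label\"?$", cols)
  broken <- vapply(lines[header_idx:length(lines)], function(l) {
    paste(strsplit(l, ",")[[1]][keep], collapse = ",")
  }, character(1), USE.NAMES = FALSE)
  writeLines(c(lines[seq_len(header_idx - 1)], broken), path)
  expect_error(read_session(path), "label")
  unlink(path)
})

test_that("cohort generation gives distinct deterministic participants", {
  co <- generate_cohort(3, seed = 4)
  expect_equal(vapply(co, function(s) s$participant_id, character(1)),
               c("P1", "P2", "P3"))
  expect_false(identical(co[[1]]$channels, co[[2]]$channels))
  co2 <- generate_cohort(4, seed = 4)
  # counter-based seeds: adding a participant leaves the others unchanged
  expect_identical(co[[2]]$channels, co2[[2]]$channels)
})
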