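#' Read and validate a YAML run configuration
#'
#' A run configuration fully determines a reproducible run: master `seed`,
#' `n_participants`, `out_dir`, and optional analysis settings
#' (`session` overrides passed to [session_config()], `window_frames`,
#' `families`, `subsets`, `stats`, `k_best`).
#'
#' @param path Path to a YAML file.
#' @return Named list of class `nirs_run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  required <- c("seed", "n_participants", "out_dir")
  for (field in required) {
    if (is.null(cfg[[field]])) stop("missing config field: ", field)
  }
  defaults <- list(window_frames = 100, families = c("SVM_LINEAR", "RF"),
                   subsets = "ALL", stats = c("max", "mean"), k_best = 10,
                   session = list())
  for (nm in names(defaults)) {
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  }
  structure(cfg, class = "nirs_run_config")
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(cfg), tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Run a pipeline stage from a configuration
#'
#' Thin orchestration over the package's functions. Subcommands:
#' `"synth"` writes one CSV session per participant; `"train"` fits a
#' per-participant pipeline on trial groups 1-2 and serialises the bundle;
#' `"replay"` replays each frozen pipeline over its participant's test
#' group and writes per-window predictions; `"loocv"` runs the
#' cross-participant analysis and writes fold and pooled tables;
#' `"report"` summarises an existing loocv output as a family x window
#' table. Every run writes `manifest_<task>.json` (config hash, seed,
#' package version, files); identical config + seed reproduce identical
#' outputs.
#'
#' @param config A [read_run_config()] object (or path to the YAML file).
#' @param task One of `"synth"`, `"train"`, `"replay"`, `"loocv"`,
#'   `"report"`.
#' @return Invisible character vector of files written.
#' @export
fnirs_run <- function(config, task = c("synth", "train", "replay", "loocv",
                                       "report")) {
  task <- match.arg(task)
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "nirs_run_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)

  session_paths <- function() {
    file.path(out, sprintf("session_P%d.csv", seq_len(config$n_participants)))
  }
  load_sessions <- function() {
    paths <- session_paths()
    if (!all(file.exists(paths))) {
      stop("session files missing; run the synth task first")
    }
    lapply(paths, read_session)
  }

  if (task == "synth") {
    sessions <- generate_cohort(config$n_participants, config$seed,
                                config_args = config$session)
    paths <- session_paths()
    for (i in seq_along(sessions)) write_session(sessions[[i]], paths[i])
    files <- paths
  } else if (task == "train") {
    sessions <- load_sessions()
    for (s in sessions) {
      pl <- train_pipeline(s, window_frames = config$window_frames,
                           stats = config$stats, k_best = config$k_best,
                           train_groups = 1:2, seed = config$seed)
      d <- file.path(out, paste0("pipeline_", s$participant_id))
      write_pipeline(pl, d)
      files <- c(files, file.path(d, c("pipeline.json", "classifier.rds")))
    }
  } else if (task == "replay") {
    sessions <- load_sessions()
    rows <- list()
    for (s in sessions) {
      pl <- read_pipeline(file.path(out, paste0("pipeline_",
                                                s$participant_id)))
      rep <- online_replay(pl, s)
      df <- rep$predictions
      df$participant <- s$participant_id
      rows[[length(rows) + 1]] <- df
    }
    path <- file.path(out, "replay_predictions.csv")
    utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
    files <- path
  } else if (task == "loocv") {
    sessions <- load_sessions()
    cv <- loocv(sessions, families = config$families,
                window_frames = config$window_frames,
                subsets = config$subsets, seed = config$seed)
    f1 <- file.path(out, "loocv_folds.csv")
    f2 <- file.path(out, "loocv_pooled.csv")
    utils::write.csv(cv$folds, f1, row.names = FALSE)
    utils::write.csv(cv$pooled, f2, row.names = FALSE)
    files <- c(f1, f2)
  } else if (task == "report") {
    path <- file.path(out, "loocv_pooled.csv")
    if (!file.exists(path)) stop("loocv output missing; run loocv first")
    pooled <- utils::read.csv(path)
    for (subset in unique(pooled$subset)) {
      df <- pooled[pooled$subset == subset, ]
      tab <- summarize_window_sweep(
        data.frame(family = df$family, window = df$window,
                   macro_f1 = df$macro_f1_pooled))
      f <- file.path(out, paste0("sweep_", subset, ".csv"))
      utils::write.csv(as.data.frame(tab), f)
      files <- c(files, f)
    }
  }

  manifest <- list(task = task, seed = config$seed,
                   config_md5 = config_hash(config),
                   package_version = as.character(utils::packageVersion("nirsbci")),
                   files = basename(files))
  mpath <- file.path(out, paste0("manifest_", task, ".json"))
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA)
  invisible(c(files, mpath))
}
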