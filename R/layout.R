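#' @keywords internal
"_PACKAGE"

## Task label vocabulary used throughout the package. Class order is fixed:
## visualization = class 0, workload = class 1.
TASK_LEVELS <- c("visualization", "workload")
REST_LABEL <- "rest"
SIDE_LEVELS <- c("lateral", "medial")

#' Default prefrontal probe layout
#'
#' Builds the optode geometry of a single-detector prefrontal probe: six long
#' source positions (three over a relatively lateral and three over a
#' relatively medial aspect of left Brodmann 10) and two short (1.5 cm)
#' positions, one per side, used purely as superficial-physiology regressors.
#' Per side, two long positions sit at 3.0 cm from the detector and one at
#' 3.61 cm. Every position emits at both 690 nm and 830 nm.
#'
#' @return An object of class `nirs_layout`: a list with
#'   `positions` (data frame: `position`, `side`, `type`, `distance_cm`),
#'   `wavelengths_nm`, `detector`, and `short_map` (short position ->
#'   integer vector of the three long positions on its side).
#' @examples
#' layout <- make_default_layout()
#' subset(layout$positions, type == "short")
#' @export
make_default_layout <- function() {
  positions <- data.frame(
    position = 1:8,
    side = c(rep("lateral", 3), rep("medial", 3), "lateral", "medial"),
    type = c(rep("long", 6), "short", "short"),
    distance_cm = c(3.0, 3.0, 3.61, 3.0, 3.0, 3.61, 1.5, 1.5),
    stringsAsFactors = FALSE
  )
  layout <- structure(
    list(
      positions = positions,
      wavelengths_nm = c(690, 830),
      detector = "B",
      short_map = list(`7` = 1:3, `8` = 4:6)
    ),
    class = "nirs_layout"
  )
  validate_layout(layout)
  layout
}

validate_layout <- function(layout) {
  p <- layout$positions
  long <- p[p$type == "long", ]
  short <- p[p$type == "short", ]
  stopifnot(
    nrow(long) == 6, nrow(short) == 2,
    all(table(long$side) == 3),
    all(short$distance_cm == 1.5),
    all(long$distance_cm %in% c(3.0, 3.61)),
    sum(long$distance_cm == 3.61) == 2,
    length(layout$wavelengths_nm) == 2
  )
  mapped <- sort(unlist(layout$short_map, use.names = FALSE))
  stopifnot(identical(mapped, long$position))
  for (s in names(layout$short_map)) {
    s_side <- p$side[p$position == as.integer(s)]
    covered <- layout$short_map[[s]]
    stopifnot(length(covered) == 3,
              all(p$side[match(covered, p$position)] == s_side))
  }
  invisible(layout)
}

#' @export
print.nirs_layout <- function(x, ...) {
  cat("fNIRS probe layout (detector ", x$detector, ")\n", sep = "")
  cat("  wavelengths:", paste(x$wavelengths_nm, collapse = "/"), "nm\n")
  print(x$positions, row.names = FALSE)
  invisible(x)
}

#' Block-design task protocol
#'
#' Three groups of task blocks; each group is one visualization block, a
#' 2 min rest, one workload block, and a 2 min rest. The first two groups are
#' flagged as training data and the third as the (real-time) test group.
#'
#' @param task_block_duration_s Duration of each task block in seconds.
#' @param rest_duration_s Rest duration in seconds (default 120).
#' @return An object of class `nirs_protocol`: a data frame with columns
#'   `block`, `group`, `task`, `duration_s`, `role` (`"train"`/`"test"`).
#' @examples
#' make_protocol(60)
#' @export
make_protocol <- function(task_block_duration_s = 60, rest_duration_s = 120) {
  if (!is.numeric(task_block_duration_s) || task_block_duration_s <= 0) {
    stop("task_block_duration_s must be a positive number")
  }
  tasks <- rep(c(TASK_LEVELS[1], REST_LABEL, TASK_LEVELS[2], REST_LABEL), 3)
  proto <- data.frame(
    block = seq_along(tasks),
    group = rep(1:3, each = 4),
    task = tasks,
    duration_s = ifelse(tasks == REST_LABEL, rest_duration_s,
                        task_block_duration_s),
    stringsAsFactors = FALSE
  )
  proto$role <- ifelse(proto$group <= 2, "train", "test")
  structure(proto, class = c("nirs_protocol", "data.frame"))
}

## Fixed rounding rule for converting a duration to a sample count; the tiny
## epsilon guards against 5.8 not being representable in binary.
n_samples_for <- function(duration_s, fs_hz) {
  as.integer(floor(duration_s * fs_hz + 1e-9))
}
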