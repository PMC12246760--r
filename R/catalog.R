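# Aggregator sets. Swipe-level scalar metrics get the full set of eight
# statistical functions; pressure metrics drop `first` (the opening swipe
# of a session reflects initial grip adjustment rather than steady-state
# play); free-running sequences (pooled touch traces, sensor streams) get
# the six order-free aggregators, since "first"/"last" have no behavioural
# meaning for streams that are not aligned to swipe onsets.
AGG_FULL <- c("mean", "median", "max", "min", "std", "range", "first", "last")
AGG_PRESS <- c("mean", "median", "max", "min", "std", "range", "last")
AGG_STREAM <- c("mean", "median", "std", "min", "max", "range")

BASES_KINEMATIC <- c("swipe_start_posX", "swipe_start_posY", "swipe_end_posX",
                     "swipe_end_posY", "swipe_speed", "swipe_duration",
                     "swipe_distance", "time_between_swipes")
BASES_PRESS <- c("swipe_start_press", "swipe_end_press",
                 "swipe_start_press_variance", "swipe_end_press_variance",
                 "swipe_press", "swipe_press_variance")
BASES_TRACE <- c("swipe_posX", "swipe_posY")
BASES_SENSOR <- c("acl_X", "acl_Y", "acl_Z", "gyro_X", "gyro_Y", "gyro_Z")

BASE_DEFINITIONS <- c(
  swipe_start_posX = "x coordinate of the screen touch when the swipe started",
  swipe_start_posY = "y coordinate of the screen touch when the swipe started",
  swipe_end_posX = "x coordinate of the screen touch when the swipe ended",
  swipe_end_posY = "y coordinate of the screen touch when the swipe ended",
  swipe_posX = "x coordinates of every touch point along the swipe traces",
  swipe_posY = "y coordinates of every touch point along the swipe traces",
  swipe_start_press = "contact-area pressure when the swipe started",
  swipe_end_press = "contact-area pressure when the swipe ended",
  swipe_start_press_variance = "variance of the pressure while the swipe was starting",
  swipe_end_press_variance = "variance of the pressure while the swipe was ending",
  swipe_press = "average pressure over the duration of the swipe",
  swipe_press_variance = "overall pressure variance over the duration of the swipe",
  swipe_speed = "swipe speed: total path length divided by duration (px/s)",
  swipe_duration = "seconds taken to complete the swipe",
  swipe_distance = "total screen distance covered by the swipe path (px)",
  time_between_swipes = "seconds elapsed since the end of the previous swipe",
  acl_X = "accelerometer x-axis reading (m/s^2)",
  acl_Y = "accelerometer y-axis reading (m/s^2)",
  acl_Z = "accelerometer z-axis reading (m/s^2)",
  gyro_X = "gyroscope x-axis reading (rad/s)",
  gyro_Y = "gyroscope y-axis reading (rad/s)",
  gyro_Z = "gyroscope z-axis reading (rad/s)"
)

#' Build the per-game feature catalog
#'
#' Enumerates the aggregated session features for one game: each per-swipe
#' base metric crossed with its applicable aggregators, pooled touch-trace
#' positions and sensor axes with the six order-free aggregators, the
#' retained swipe count, and (puzzle/runner only, where swipes are
#' quantized to four directions) per-direction swipe counts. The catalog
#' is deterministic and ordered; feature names are
#' `<base>_<aggregator>`.
#'
#' @param game `"puzzle"`, `"runner"` or `"slicer"`.
#' @return Data frame with columns `feature_name`, `base`, `aggregator`,
#'   `definition`, and attribute `"game"`.
#' @export
build_catalog <- function(game) {
  game <- match.arg(game, GAMES)
  rows <- list()
  push <- function(base, aggs, def) {
    rows[[length(rows) + 1L]] <<- data.frame(
      feature_name = paste0(base, "_", aggs), base = base, aggregator = aggs,
      definition = paste0(def, " - per-session ", aggs),
      stringsAsFactors = FALSE
    )
  }
  for (b in BASES_KINEMATIC) push(b, AGG_FULL, BASE_DEFINITIONS[[b]])
  for (b in BASES_PRESS) push(b, AGG_PRESS, BASE_DEFINITIONS[[b]])
  for (b in BASES_TRACE) push(b, AGG_STREAM, BASE_DEFINITIONS[[b]])
  if (game != "slicer") {
    rows[[length(rows) + 1L]] <- data.frame(
      feature_name = paste0("swipe_count_", DIRECTIONS),
      base = "swipe_count", aggregator = DIRECTIONS,
      definition = paste0("number of retained swipes in direction ", DIRECTIONS),
      stringsAsFactors = FALSE
    )
  }
  for (b in BASES_SENSOR) push(b, AGG_STREAM, BASE_DEFINITIONS[[b]])
  rows[[length(rows) + 1L]] <- data.frame(
    feature_name = "swipe_count", base = "swipe", aggregator = "count",
    definition = "total number of retained swipes in the session",
    stringsAsFactors = FALSE
  )
  cat_df <- do.call(rbind, rows)
  rownames(cat_df) <- NULL
  stopifnot(!anyDuplicated(cat_df$feature_name),
            nrow(cat_df) >= 140, nrow(cat_df) <= 160)
  attr(cat_df, "game") <- game
  cat_df
}

#' Export a feature catalog as CSV
#'
#' @param catalog Output of [build_catalog()].
#' @param path Output CSV path.
#' @export
write_catalog <- function(catalog, path) {
  utils::write.csv(catalog, path, row.names = FALSE)
  invisible(path)
}
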