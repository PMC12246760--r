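#' Cleaning configuration
#'
#' @param min_swipe_distance Minimum path length in px for a touch to count
#'   as an intentional swipe rather than a tap or false touch (default 20).
#' @param iqr_multiplier Tukey fence multiplier for outlier removal
#'   (default 1.5).
#' @param iqr_scope `"per_participant_metric"` (filter each participant's
#'   per-swipe value sequence before aggregation, the default) or
#'   `"pooled_metric"` (filter each aggregated feature across participants
#'   instead).
#' @param speed_mode `"path"` (speed = path length / duration, matching the
#'   definition of swipe distance as total screen covered) or
#'   `"displacement"` for sensitivity analyses.
#' @return A `cleaning_config` list.
#' @export
cleaning_config <- function(min_swipe_distance = 20, iqr_multiplier = 1.5,
                            iqr_scope = c("per_participant_metric", "pooled_metric"),
                            speed_mode = c("path", "displacement")) {
  stopifnot(min_swipe_distance >= 0, iqr_multiplier > 0)
  structure(list(
    min_swipe_distance = min_swipe_distance,
    iqr_multiplier = iqr_multiplier,
    iqr_scope = match.arg(iqr_scope),
    speed_mode = match.arg(speed_mode)
  ), class = "cleaning_config")
}

#' Quantize a swipe displacement to one of four directions
#'
#' Dominant-axis rule: the larger absolute component wins; on an exact tie
#' the horizontal axis wins. Only used for the puzzle and runner games,
#' whose gameplay admits four swipe directions.
#'
#' @param dx,dy Displacement components in px (bottom-left origin, y up).
#' @return One of `"up"`, `"down"`, `"left"`, `"right"` (vectorized).
#' @export
quantize_direction <- function(dx, dy) {
  if (any(dx == 0 & dy == 0)) stop("zero displacement has no direction", call. = FALSE)
  ifelse(abs(dx) >= abs(dy),
         ifelse(dx > 0, "right", "left"),
         ifelse(dy > 0, "up", "down"))
}

#' Derive per-swipe kinematics from a touch trace
#'
#' Recomputes every stored swipe metric from the raw path: distance is the
#' sum of consecutive segment lengths, duration the time span of the trace,
#' speed distance/duration (or net displacement/duration in
#' `"displacement"` mode), pressure mean/variance over all points, and
#' start/end pressure taken from the first/last point with their local
#' variances over the first/last `k = 5` points (all points when fewer).
#'
#' @param path Data frame of touch points `t, x, y, press` (>= 2 points,
#'   positive time span); `t` is seconds since swipe start.
#' @param anchors List with `swipe_id`, `event_time`, `start_time`, and
#'   optionally `time_between_swipes`.
#' @param game Game archetype; slicer swipes carry direction `"none"`.
#' @param config A [cleaning_config()] (for `speed_mode`).
#' @return One-row data frame of swipe metrics (see `SWIPE_COLUMNS`).
#' @export
derive_swipe_metrics <- function(path, anchors, game,
                                 config = cleaning_config()) {
  game <- match.arg(game, GAMES)
  n <- nrow(path)
  dur <- path$t[n] - path$t[1]
  if (n < 2 || dur <= 0) {
    stop("tap rejected: swipe trace needs >= 2 points spanning positive time",
         call. = FALSE)
  }
  dist <- sum(sqrt(diff(path$x)^2 + diff(path$y)^2))
  disp <- sqrt((path$x[n] - path$x[1])^2 + (path$y[n] - path$y[1])^2)
  speed <- (if (config$speed_mode == "path") dist else disp) / dur
  k <- min(5L, n)
  var0 <- function(v) if (length(v) > 1) stats::var(v) else 0
  data.frame(
    swipe_id = as.integer(anchors$swipe_id),
    event_time = anchors$event_time,
    start_time = anchors$start_time,
    end_time = anchors$start_time + dur,
    start_x = path$x[1], start_y = path$y[1],
    end_x = path$x[n], end_y = path$y[n],
    start_press = path$press[1], end_press = path$press[n],
    start_press_variance = var0(path$press[seq_len(k)]),
    end_press_variance = var0(path$press[seq.int(n - k + 1L, n)]),
    press_mean = mean(path$press), press_variance = var0(path$press),
    speed = speed, duration = dur, distance = dist,
    direction = if (game == "slicer") "none" else
      quantize_direction(path$x[n] - path$x[1], path$y[n] - path$y[1]),
    time_between_swipes = anchors$time_between_swipes %||% NA_real_,
    stringsAsFactors = FALSE
  )
}

#' Remove menu interactions and sub-threshold touches
#'
#' Retains swipes whose `event_time` falls inside the session's gameplay
#' window and whose path length reaches `min_swipe_distance`; everything
#' else (menu navigation before/after gameplay, taps, palm grazes) is
#' dropped. The removal log counts drops by reason.
#'
#' @param session A `game_session`.
#' @param config A [cleaning_config()].
#' @return The cleaned session, with attribute `"removal_log"` (named
#'   counts: `menu`, `sub_threshold`).
#' @export
clean_swipes <- function(session, config = cleaning_config()) {
  stopifnot(inherits(session, "game_session"))
  sw <- session$swipes
  if (nrow(sw) == 0) {
    attr(session, "removal_log") <- c(menu = 0L, sub_threshold = 0L)
    return(session)
  }
  in_window <- sw$event_time >= session$gameplay_window[1] &
    sw$event_time <= session$gameplay_window[2]
  long_enough <- sw$distance >= config$min_swipe_distance
  keep <- in_window & long_enough
  log <- c(menu = sum(!in_window),
           sub_threshold = sum(in_window & !long_enough))
  session$swipes <- sw[keep, , drop = FALSE]
  rownames(session$swipes) <- NULL
  session$paths <- session$paths[session$paths$swipe_id %in% session$swipes$swipe_id, ,
                                 drop = FALSE]
  attr(session, "removal_log") <- log
  session
}

#' Tukey IQR outlier filter
#'
#' Removes values outside `[Q1 - m * IQR, Q3 + m * IQR]`, with quartiles by
#' the linear-interpolation rule (R quantile type 7). Sequences shorter
#' than 4 pass through unchanged; retained values keep their order.
#'
#' @param values Numeric vector (no missing values).
#' @param multiplier Fence multiplier `m` (default 1.5).
#' @return List with `values` (retained subsequence) and `outlier` (logical
#'   mask on the input, `TRUE` = removed).
#' @export
iqr_filter <- function(values, multiplier = 1.5) {
  stopifnot(multiplier > 0)
  n <- length(values)
  if (n < 4) {
    return(list(values = values, outlier = rep(FALSE, n)))
  }
  qs <- stats::quantile(values, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- qs[2] - qs[1]
  out <- values < qs[1] - multiplier * iqr | values > qs[2] + multiplier * iqr
  list(values = values[!out], outlier = out)
}

# the eight statistical functions (sample SD); input must be NA-free
agg_stats <- function(v, aggs) {
  n <- length(v)
  vapply(aggs, function(a) {
    if (n == 0) return(NA_real_)
    switch(a,
      mean = mean(v), median = stats::median(v), max = max(v), min = min(v),
      std = if (n > 1) stats::sd(v) else 0, range = max(v) - min(v),
      first = v[1], last = v[n],
      stop("unknown aggregator ", a))
  }, numeric(1))
}

# per-swipe base metric sequences, ordered by event_time
base_sequences <- function(session) {
  sw <- session$swipes
  ord <- order(sw$event_time, sw$swipe_id)
  sw <- sw[ord, , drop = FALSE]
  pp <- session$paths
  pord <- order(match(pp$swipe_id, sw$swipe_id), pp$t)
  pp <- pp[pord, , drop = FALSE]
  tbs <- sw$time_between_swipes
  list(
    swipe_start_posX = sw$start_x, swipe_start_posY = sw$start_y,
    swipe_end_posX = sw$end_x, swipe_end_posY = sw$end_y,
    swipe_speed = sw$speed, swipe_duration = sw$duration,
    swipe_distance = sw$distance,
    time_between_swipes = tbs[!is.na(tbs)],
    swipe_start_press = sw$start_press, swipe_end_press = sw$end_press,
    swipe_start_press_variance = sw$start_press_variance,
    swipe_end_press_variance = sw$end_press_variance,
    swipe_press = sw$press_mean, swipe_press_variance = sw$press_variance,
    swipe_posX = pp$x, swipe_posY = pp$y
  )
}

sensor_axes <- function(session) {
  ss <- session$sensors
  if (nrow(ss) == 0) {
    return(stats::setNames(rep(list(numeric(0)), 6), BASES_SENSOR))
  }
  acc <- ss$stream == "accelerometer"
  list(acl_X = ss$x[acc], acl_Y = ss$y[acc], acl_Z = ss$z[acc],
       gyro_X = ss$x[!acc], gyro_Y = ss$y[!acc], gyro_Z = ss$z[!acc])
}

#' Aggregate a cleaned session into its feature vector
#'
#' Applies each catalog aggregator to the per-swipe value sequence of its
#' base metric, after Tukey-IQR filtering of that sequence (under the
#' default `per_participant_metric` scope). Sensor axes are aggregated
#' without IQR filtering (free-running streams, order-free aggregators
#' only). A session with no retained swipes yields `swipe_count = 0` and
#' missing values for every swipe-derived feature.
#'
#' @param session A cleaned `game_session`.
#' @param catalog Catalog from [build_catalog()]; must match the session's
#'   game.
#' @param config A [cleaning_config()].
#' @return Named numeric vector over `catalog$feature_name`.
#' @export
aggregate_session <- function(session, catalog = build_catalog(session$game),
                              config = cleaning_config()) {
  stopifnot(inherits(session, "game_session"))
  if (!identical(attr(catalog, "game"), session$game)) {
    stop("catalog built for game '", attr(catalog, "game"),
         "' does not match session game '", session$game, "'", call. = FALSE)
  }
  seqs <- base_sequences(session)
  sens <- sensor_axes(session)
  filter_swipe <- config$iqr_scope == "per_participant_metric"
  out <- stats::setNames(rep(NA_real_, nrow(catalog)), catalog$feature_name)
  for (base in unique(catalog$base)) {
    aggs <- catalog$aggregator[catalog$base == base]
    names_b <- catalog$feature_name[catalog$base == base]
    if (base == "swipe") { # swipe_count
      out[names_b] <- nrow(session$swipes)
    } else if (base == "swipe_count") { # per-direction counts
      out[names_b] <- vapply(aggs, function(d) sum(session$swipes$direction == d),
                             numeric(1))
    } else if (base %in% BASES_SENSOR) {
      out[names_b] <- agg_stats(sens[[base]], aggs)
    } else {
      v <- seqs[[base]]
      if (length(v) == 0) next # all-NA for swipe-free sessions
      if (filter_swipe) v <- iqr_filter(v, config$iqr_multiplier)$values
      out[names_b] <- agg_stats(v, aggs)
    }
  }
  out
}

#' Extract the per-participant feature matrix for one game
#'
#' Runs cleaning and aggregation over a list of sessions of a single game
#' and assembles the wide feature matrix (one row per participant). Under
#' the `pooled_metric` IQR scope, Tukey filtering is instead applied to
#' each aggregated feature column across participants (flagged values are
#' set to missing).
#'
#' @param sessions List of `game_session` objects, all of the same game.
#' @param config A [cleaning_config()].
#' @param catalog Optional pre-built catalog.
#' @return Data frame: `participant_id`, `game`, then one column per
#'   catalog feature.
#' @export
extract_features <- function(sessions, config = cleaning_config(),
                             catalog = NULL) {
  stopifnot(length(sessions) > 0)
  games <- vapply(sessions, function(s) s$game, character(1))
  if (length(unique(games)) != 1) {
    stop("extract_features expects sessions from a single game", call. = FALSE)
  }
  if (is.null(catalog)) catalog <- build_catalog(games[1])
  rows <- lapply(sessions, function(s) {
    aggregate_session(clean_swipes(s, config), catalog, config)
  })
  mat <- do.call(rbind, rows)
  if (config$iqr_scope == "pooled_metric") {
    for (j in seq_len(ncol(mat))) {
      v <- mat[, j]
      ok <- !is.na(v)
      if (sum(ok) >= 4) {
        f <- iqr_filter(v[ok], config$iqr_multiplier)
        v[ok][f$outlier] <- NA_real_
        mat[, j] <- v
      }
    }
  }
  out <- data.frame(participant_id = vapply(sessions, function(s) s$participant_id,
                                            character(1)),
                    game = games[1], stringsAsFactors = FALSE)
  cbind(out, as.data.frame(mat))
}

#' Write a feature matrix as CSV
#'
#' Missing values are written as empty cells.
#'
#' @param features Output of [extract_features()].
#' @param path Output CSV path.
#' @export
write_feature_matrix <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE, na = "")
  invisible(path)
}
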