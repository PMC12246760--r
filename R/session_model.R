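# Per-swipe scalar columns carried by every session, in canonical order.
# `paths` holds the full touch traces (one row per touch point), keyed by
# swipe_id; point times are seconds since swipe start.
SWIPE_COLUMNS <- c(
  "swipe_id", "event_time", "start_time", "end_time",
  "start_x", "start_y", "end_x", "end_y",
  "start_press", "end_press", "start_press_variance", "end_press_variance",
  "press_mean", "press_variance",
  "speed", "duration", "distance", "direction", "time_between_swipes"
)

empty_swipes <- function() {
  df <- data.frame(
    swipe_id = integer(), event_time = numeric(), start_time = numeric(),
    end_time = numeric(), start_x = numeric(), start_y = numeric(),
    end_x = numeric(), end_y = numeric(), start_press = numeric(),
    end_press = numeric(), start_press_variance = numeric(),
    end_press_variance = numeric(), press_mean = numeric(),
    press_variance = numeric(), speed = numeric(), duration = numeric(),
    distance = numeric(), direction = character(),
    time_between_swipes = numeric(), stringsAsFactors = FALSE
  )
  df
}

empty_paths <- function() {
  data.frame(swipe_id = integer(), t = numeric(), x = numeric(), y = numeric(),
             press = numeric())
}

empty_sensors <- function() {
  data.frame(stream = character(), t = numeric(), x = numeric(), y = numeric(),
             z = numeric(), stringsAsFactors = FALSE)
}

#' Construct a game session
#'
#' A session is one participant x game x (at most) 15-minute play record.
#' Coordinates use a bottom-left origin in the session's orientation
#' (y grows upward, units are pixels); the pressure channel is a
#' dimensionless fingertip contact-area proxy in \[0, 1\]. `event_time` is
#' anchored at game launch, `start_time`/`end_time` at level load.
#'
#' @param participant_id Opaque participant identifier.
#' @param game One of `"puzzle"`, `"runner"`, `"slicer"`.
#' @param swipes Data frame of per-swipe scalars (see `SWIPE_COLUMNS`).
#' @param paths Data frame of touch points: `swipe_id, t, x, y, press`.
#' @param sensors Data frame of device-motion samples:
#'   `stream ("accelerometer"/"gyroscope"), t, x, y, z`.
#' @param screen_dims Width/height in pixels; defaults to the game's
#'   orientation (2400x1080 landscape, 1080x2400 portrait).
#' @param session_limit Session duration cap in seconds (default 900).
#' @param gameplay_window Launch-anchored `(start, end)` of actual gameplay;
#'   swipes outside it are menu interactions.
#' @return An object of class `game_session`.
#' @export
game_session <- function(participant_id, game,
                         swipes = empty_swipes(), paths = empty_paths(),
                         sensors = empty_sensors(),
                         screen_dims = game_screen_dims(game),
                         session_limit = 900,
                         gameplay_window = c(20, 890)) {
  game <- match.arg(game, GAMES)
  s <- structure(list(
    participant_id = as.character(participant_id),
    game = game,
    orientation = game_orientation(game),
    screen_dims = as.numeric(screen_dims),
    session_limit = as.numeric(session_limit),
    gameplay_window = as.numeric(gameplay_window),
    swipes = swipes,
    paths = paths,
    sensors = sensors
  ), class = "game_session")
  s
}

#' @export
print.game_session <- function(x, ...) {
  cat(sprintf("<game_session> %s | %s (%s, %gx%g px)\n", x$participant_id,
              x$game, x$orientation, x$screen_dims[1], x$screen_dims[2]))
  cat(sprintf("  %d swipes, %d touch points, %d sensor samples, window [%g, %g] s\n",
              nrow(x$swipes), nrow(x$paths), nrow(x$sensors),
              x$gameplay_window[1], x$gameplay_window[2]))
  invisible(x)
}

#' Validate a game session
#'
#' Pure structural check of the session invariants. Issues are returned as
#' data, never raised: each one names the field, the offending swipe (where
#' applicable), and the violated rule. A clean session yields an empty
#' vector.
#'
#' Checked rules: swipe ordering by `event_time` and `event_time <=
#' session_limit`; unique swipe ids; `end_time >= start_time` with
#' `duration` matching the difference to 1e-6; `distance` at least the
#' straight-line displacement; `speed = distance / duration`; direction set
#' for puzzle/runner swipes and `"none"` for the slicer; touch-point times
#' nonnegative and nondecreasing within a swipe; coordinates within the
#' screen; pressures within \[0, 1\]; orientation consistent with the game.
#'
#' @param session A `game_session`.
#' @return Character vector of issue descriptions (empty when valid).
#' @export
validate_session <- function(session) {
  stopifnot(inherits(session, "game_session"))
  issues <- character()
  add <- function(...) issues <<- c(issues, sprintf(...))

  if (session$orientation != game_orientation(session$game)) {
    add("orientation: %s session must be %s, found %s", session$game,
        game_orientation(session$game), session$orientation)
  }
  sw <- session$swipes
  if (nrow(sw) == 0) return(issues)

  if (is.unsorted(sw$event_time)) {
    add("event_time: swipes not ordered by event_time")
  }
  if (anyDuplicated(sw$swipe_id)) {
    add("swipe_id: duplicate ids %s",
        paste(unique(sw$swipe_id[duplicated(sw$swipe_id)]), collapse = ","))
  }
  late <- sw$swipe_id[sw$event_time > session$session_limit]
  for (id in late) add("event_time: swipe %d after session_limit", id)

  bad <- sw$swipe_id[sw$end_time < sw$start_time]
  for (id in bad) add("end_time: swipe %d has end_time < start_time", id)

  dd <- abs(sw$duration - (sw$end_time - sw$start_time))
  for (id in sw$swipe_id[dd > 1e-6]) {
    add("duration: swipe %d duration != end_time - start_time", id)
  }
  disp <- sqrt((sw$end_x - sw$start_x)^2 + (sw$end_y - sw$start_y)^2)
  for (id in sw$swipe_id[sw$distance < disp - 1e-6]) {
    add("distance: swipe %d distance below start-end displacement", id)
  }
  ok_dur <- sw$duration > 0
  sp <- abs(sw$speed - sw$distance / sw$duration)
  for (id in sw$swipe_id[ok_dur & sp > pmax(1e-6, 1e-9 * sw$speed)]) {
    add("speed: swipe %d speed != distance / duration", id)
  }
  if (session$game == "slicer") {
    for (id in sw$swipe_id[sw$direction != "none"]) {
      add("direction: swipe %d has direction '%s' but slicer swipes carry none",
          id, sw$direction[sw$swipe_id == id][1])
    }
  } else {
    for (id in sw$swipe_id[!sw$direction %in% DIRECTIONS]) {
      add("direction: swipe %d lacks a quantized direction (puzzle/runner rule)", id)
    }
  }

  pp <- session$paths
  if (nrow(pp)) {
    if (any(pp$t < 0)) add("path t: negative touch-point time")
    ord <- order(match(pp$swipe_id, sw$swipe_id))
    ts <- pp$t[ord]
    grp <- pp$swipe_id[ord]
    dec <- which(diff(ts) < 0 & diff(as.integer(factor(grp, levels = unique(grp)))) == 0)
    for (id in unique(grp[dec])) add("path t: swipe %d touch times decrease", id)
    if (any(pp$x < 0 | pp$x > session$screen_dims[1] |
            pp$y < 0 | pp$y > session$screen_dims[2])) {
      add("path x/y: touch point outside screen bounds")
    }
    if (any(pp$press < 0 | pp$press > 1)) add("path press: pressure outside [0, 1]")
  }
  issues
}
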