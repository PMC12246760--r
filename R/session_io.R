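# JSON field names for one swipe object, as logged by the games.
JSON_SWIPE_FIELDS <- c(
  "swipe_ID", "swipe_event_time", "swipe_start_time", "swipe_end_time",
  "swipe_start_pos", "swipe_end_pos", "swipe_pos",
  "swipe_start_press", "swipe_end_press",
  "swipe_start_press_variance", "swipe_end_press_variance",
  "swipe_press", "swipe_press_variance",
  "swipe_speed", "swipe_duration", "swipe_distance",
  "swipe_direction", "time_between_swipes"
)

# internal column <-> JSON key mapping for scalar swipe fields
SWIPE_JSON_SCALARS <- c(
  swipe_id = "swipe_ID", event_time = "swipe_event_time",
  start_time = "swipe_start_time", end_time = "swipe_end_time",
  start_press = "swipe_start_press", end_press = "swipe_end_press",
  start_press_variance = "swipe_start_press_variance",
  end_press_variance = "swipe_end_press_variance",
  press_mean = "swipe_press", press_variance = "swipe_press_variance",
  speed = "swipe_speed", duration = "swipe_duration",
  distance = "swipe_distance", direction = "swipe_direction",
  time_between_swipes = "time_between_swipes"
)

#' Write a session log
#'
#' Serializes a session to the JSON event-log dialect (documented by the
#' schema at `system.file("extdata", "session_log.schema.json", package =
#' "swipesense")`). Keys are emitted in a fixed order and numbers at full
#' precision, so writing the same session twice produces byte-identical
#' files and a read-back reproduces the session to better than 1e-9.
#'
#' @param session A valid `game_session`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_session_log <- function(session, path) {
  stopifnot(inherits(session, "game_session"))
  sw <- session$swipes
  pp <- session$paths
  pp_split <- split(pp[, c("t", "x", "y", "press")],
                    factor(pp$swipe_id, levels = sw$swipe_id))
  swipe_objs <- lapply(seq_len(nrow(sw)), function(i) {
    pts <- pp_split[[i]]
    obj <- list(
      swipe_ID = sw$swipe_id[i],
      swipe_event_time = sw$event_time[i],
      swipe_start_time = sw$start_time[i],
      swipe_end_time = sw$end_time[i],
      swipe_start_pos = c(sw$start_x[i], sw$start_y[i]),
      swipe_end_pos = c(sw$end_x[i], sw$end_y[i]),
      # touch trace as [t, x, y, press] quadruples (matrix -> array of rows)
      swipe_pos = unname(cbind(pts$t, pts$x, pts$y, pts$press)),
      swipe_start_press = sw$start_press[i],
      swipe_end_press = sw$end_press[i],
      swipe_start_press_variance = sw$start_press_variance[i],
      swipe_end_press_variance = sw$end_press_variance[i],
      swipe_press = sw$press_mean[i],
      swipe_press_variance = sw$press_variance[i],
      swipe_speed = sw$speed[i],
      swipe_duration = sw$duration[i],
      swipe_distance = sw$distance[i],
      swipe_direction = sw$direction[i],
      time_between_swipes = sw$time_between_swipes[i]
    )
    obj
  })
  sensors <- session$sensors
  sensor_objs <- lapply(c("accelerometer", "gyroscope"), function(stream) {
    ss <- sensors[sensors$stream == stream, , drop = FALSE]
    list(stream = stream, t = ss$t, x = ss$x, y = ss$y, z = ss$z)
  })
  doc <- list(
    participant_id = session$participant_id,
    game = session$game,
    orientation = session$orientation,
    screen_dims = session$screen_dims,
    session_limit = session$session_limit,
    gameplay_window = session$gameplay_window,
    swipes = swipe_objs,
    sensors = sensor_objs
  )
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, na = "null",
                           null = "null")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(json, con, useBytes = TRUE)
  invisible(path)
}

num1 <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x)

#' Read a session log
#'
#' Parses and validates a JSON session log. Structural problems are
#' reported as a single error listing every violation with the offending
#' field name.
#'
#' @param path Path to a session-log JSON file.
#' @return A `game_session` with swipes sorted by `swipe_event_time`.
#' @export
read_session_log <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) stop("malformed session log ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  probs <- character()
  need <- function(field, test, what) {
    if (is.null(doc[[field]]) || !test(doc[[field]])) {
      probs <<- c(probs, sprintf("%s: expected %s", field, what))
      FALSE
    } else TRUE
  }
  need("participant_id", function(x) is.character(x) && length(x) == 1, "string")
  ok_game <- need("game", function(x) is.character(x) && x %in% GAMES,
                  "one of puzzle/runner/slicer")
  need("orientation", function(x) is.character(x) &&
         x %in% c("landscape", "portrait"), "landscape or portrait")
  need("screen_dims", function(x) length(x) == 2 && all(vapply(x, num1, TRUE)),
       "numeric [width, height]")
  need("session_limit", num1, "number")
  need("gameplay_window", function(x) length(x) == 2 &&
         all(vapply(x, num1, TRUE)), "numeric [start, end]")
  if (is.null(doc$swipes) || !is.list(doc$swipes)) {
    probs <- c(probs, "swipes: expected array")
    doc$swipes <- list()
  }

  swipe_rows <- vector("list", length(doc$swipes))
  path_rows <- vector("list", length(doc$swipes))
  for (i in seq_along(doc$swipes)) {
    s <- doc$swipes[[i]]
    for (f in setdiff(JSON_SWIPE_FIELDS, c("swipe_pos", "swipe_start_pos",
                                           "swipe_end_pos", "swipe_direction",
                                           "time_between_swipes"))) {
      if (!num1(s[[f]] %||% NA)) {
        probs <- c(probs, sprintf("swipes[%d].%s: expected number", i, f))
      }
    }
    if (!is.character(s$swipe_direction %||% 1) ||
        !(s$swipe_direction %in% c(DIRECTIONS, "none"))) {
      probs <- c(probs, sprintf("swipes[%d].swipe_direction: expected up/down/left/right/none", i))
    }
    tbs <- s$time_between_swipes
    if (!is.null(tbs) && !num1(tbs)) {
      probs <- c(probs, sprintf("swipes[%d].time_between_swipes: expected number or null", i))
    }
    for (f in c("swipe_start_pos", "swipe_end_pos")) {
      if (length(s[[f]]) != 2 || !all(vapply(s[[f]], num1, TRUE))) {
        probs <- c(probs, sprintf("swipes[%d].%s: expected [x, y]", i, f))
      }
    }
    pos <- s$swipe_pos
    if (!is.list(pos) ||
        !all(vapply(pos, function(p) length(p) == 4 && all(vapply(p, num1, TRUE)), TRUE))) {
      probs <- c(probs, sprintf("swipes[%d].swipe_pos: expected array of [t, x, y, press]", i))
      pos <- list()
    }
    if (length(probs)) next
    m <- matrix(unlist(pos), ncol = 4, byrow = TRUE)
    path_rows[[i]] <- data.frame(swipe_id = as.integer(s$swipe_ID),
                                 t = m[, 1], x = m[, 2], y = m[, 3], press = m[, 4])
    swipe_rows[[i]] <- data.frame(
      swipe_id = as.integer(s$swipe_ID), event_time = s$swipe_event_time,
      start_time = s$swipe_start_time, end_time = s$swipe_end_time,
      start_x = s$swipe_start_pos[[1]], start_y = s$swipe_start_pos[[2]],
      end_x = s$swipe_end_pos[[1]], end_y = s$swipe_end_pos[[2]],
      start_press = s$swipe_start_press, end_press = s$swipe_end_press,
      start_press_variance = s$swipe_start_press_variance,
      end_press_variance = s$swipe_end_press_variance,
      press_mean = s$swipe_press, press_variance = s$swipe_press_variance,
      speed = s$swipe_speed, duration = s$swipe_duration,
      distance = s$swipe_distance, direction = s$swipe_direction,
      time_between_swipes = if (is.null(tbs)) NA_real_ else tbs,
      stringsAsFactors = FALSE
    )
  }

  sensor_rows <- list()
  if (!is.null(doc$sensors)) {
    for (i in seq_along(doc$sensors)) {
      st <- doc$sensors[[i]]
      if (!is.character(st$stream %||% 1) ||
          !(st$stream %in% c("accelerometer", "gyroscope"))) {
        probs <- c(probs, sprintf("sensors[%d].stream: expected accelerometer or gyroscope", i))
        next
      }
      lens <- lengths(st[c("t", "x", "y", "z")])
      if (length(unique(lens)) != 1) {
        probs <- c(probs, sprintf("sensors[%d]: t/x/y/z lengths differ", i))
        next
      }
      nlen <- length(st$t)
      if (nlen == 0) next
      sensor_rows[[i]] <- data.frame(
        stream = rep(st$stream, nlen), t = unlist(st$t), x = unlist(st$x),
        y = unlist(st$y), z = unlist(st$z), stringsAsFactors = FALSE
      )
    }
  }
  if (length(probs)) {
    stop("invalid session log ", path, ":\n  ", paste(probs, collapse = "\n  "),
         call. = FALSE)
  }
  swipes <- if (length(swipe_rows)) do.call(rbind, swipe_rows) else empty_swipes()
  paths <- if (length(path_rows)) do.call(rbind, path_rows) else empty_paths()
  ord <- order(swipes$event_time, swipes$swipe_id)
  swipes <- swipes[ord, , drop = FALSE]
  rownames(swipes) <- NULL
  sensors <- if (length(sensor_rows)) do.call(rbind, sensor_rows) else empty_sensors()
  if (!ok_game) stop("invalid session log ", path, call. = FALSE)
  game_session(doc$participant_id, doc$game, swipes = swipes, paths = paths,
               sensors = sensors,
               screen_dims = unlist(doc$screen_dims),
               session_limit = doc$session_limit,
               gameplay_window = unlist(doc$gameplay_window))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Link gameplay sessions to questionnaire records
#'
#' Joins sessions and questionnaire rows on `participant_id`. Only
#' participants with at least one session and complete GAD-7 and PHQ-8
#' responses enter the analysis; everything else is recorded in the drop
#' log with a reason. Conflicting duplicate questionnaire rows for one id
#' are an error (identical duplicates collapse).
#'
#' @param sessions List of `game_session` objects.
#' @param questionnaires Questionnaire data frame
#'   (see [read_questionnaire_table()]).
#' @return A list of cohort records (each: `participant_id`, `sessions`
#'   keyed by game, `questionnaire` row), with the drop log as attribute
#'   `"drop_log"` (data frame: `participant_id`, `reason`).
#' @export
link_records <- function(sessions, questionnaires) {
  sess_ids <- vapply(sessions, function(s) s$participant_id, character(1))
  if (any(!nzchar(sess_ids))) stop("session without participant_id", call. = FALSE)
  if (!"participant_id" %in% names(questionnaires)) {
    stop("questionnaire table lacks participant_id", call. = FALSE)
  }
  q <- questionnaires
  dup <- unique(q$participant_id[duplicated(q$participant_id)])
  for (id in dup) {
    rows <- q[q$participant_id == id, , drop = FALSE]
    if (nrow(unique(rows)) > 1) {
      stop("conflicting questionnaire rows for participant ", id, call. = FALSE)
    }
  }
  q <- q[!duplicated(q$participant_id), , drop = FALSE]

  item_cols <- c(paste0("gad7_q", 1:7), paste0("phq8_q", 1:8))
  drop <- list()
  records <- list()
  for (id in unique(sess_ids)) {
    qrow <- q[q$participant_id == id, , drop = FALSE]
    if (nrow(qrow) == 0) {
      drop[[length(drop) + 1L]] <- data.frame(participant_id = id,
                                              reason = "no questionnaire record")
      next
    }
    if (anyNA(qrow[, item_cols])) {
      drop[[length(drop) + 1L]] <- data.frame(participant_id = id,
                                              reason = "incomplete questionnaire items")
      next
    }
    sess <- sessions[sess_ids == id]
    names(sess) <- vapply(sess, function(s) s$game, character(1))
    records[[length(records) + 1L]] <- list(
      participant_id = id, sessions = sess, questionnaire = qrow
    )
  }
  for (id in setdiff(q$participant_id, sess_ids)) {
    drop[[length(drop) + 1L]] <- data.frame(participant_id = id,
                                            reason = "no gameplay sessions")
  }
  drop_log <- if (length(drop)) do.call(rbind, drop) else
    data.frame(participant_id = character(), reason = character())
  attr(records, "drop_log") <- drop_log
  records
}
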