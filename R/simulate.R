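# ---------------------------------------------------------------------------
# Synthetic cohort generator: latent severity traits -> item responses and
# per-participant swipe parameters -> full per-game event streams.
# ---------------------------------------------------------------------------

#' Default planted-effect map
#'
#' Each entry plants one feature-instrument association: the participant's
#' latent severity trait shifts the swipe parameter named in `mechanism`,
#' so that the full pipeline (synthesize -> clean -> IQR -> aggregate ->
#' Spearman) recovers `target` as the mean correlation across cohorts.
#' `latent_rho` is the calibrated trait-parameter rank coupling that
#' achieves the target end to end (see [calibrate_effect()]); the
#' pipeline attenuates it through item noise, discretization, and session
#' aggregation. The default entries are the strongest reported
#' associations of each game archetype: slower swipes and flatter
#' end-of-swipe pressure variability with higher severity on the puzzle
#' and runner games, and a raised minimum start height / pressure floor on
#' the slicer.
#'
#' @return Data frame: `game`, `feature`, `instrument`, `target`,
#'   `latent_rho`, `mechanism`.
#' @export
default_effect_map <- function() {
  data.frame(
    game = c("puzzle", "puzzle", "puzzle", "runner", "slicer", "slicer"),
    feature = c("swipe_speed_mean", "swipe_speed_mean",
                "swipe_end_press_variance_mean", "swipe_end_press_variance_mean",
                "swipe_start_posY_min", "swipe_press_min"),
    instrument = c("PHQ8", "GAD7", "PHQ8", "PHQ8", "PHQ8", "GAD7"),
    target = c(-0.405, -0.400, -0.425, -0.405, 0.368, 0.430),
    latent_rho = c(0.464, 0.461, 0.502, 0.457, 0.413, 0.484),
    mechanism = c("speed", "speed", "end_press_amp", "end_press_amp",
                  "start_posY_floor", "press_floor"),
    stringsAsFactors = FALSE
  )
}

# mechanism parameters every profile carries, per game
PROFILE_PARAMS <- c("speed", "end_press_amp", "press_level", "press_floor",
                    "start_posY_floor", "motion_amp")

#' Cohort generator configuration
#'
#' Defaults emulate the study conditions: 82 participants, three
#' 15-minute sessions each (puzzle and slicer landscape, runner portrait),
#' questionnaire totals with sample moments 9.09 (SD 5.26) for GAD-7 and
#' 8.24 (SD 4.95) for PHQ-8, and the planted-effect map of
#' [default_effect_map()]. The two severity traits are bivariate standard
#' normal with correlation `latent_cor`.
#'
#' The item-response constants (`a0`, `a1`, `sigma`; item rating =
#' `clamp(round(a0 + a1 * trait + noise), 0, 3)`) were calibrated once by
#' simulation so the totals reproduce those sample moments.
#' All per-swipe scales (speeds, pressures, path lengths) are invented
#' defaults: the source tables report correlations, not raw-signal
#' distributions.
#'
#' @param n_participants Cohort size (default 82).
#' @param seed Master RNG seed; every draw derives from it.
#' @param latent_cor Correlation between the anxiety and depression traits.
#' @param games Which game sessions to synthesize (default all three;
#'   questionnaire draws are sub-seeded independently, so restricting
#'   games leaves the questionnaire table unchanged).
#' @param swipes_per_session Poisson means of retained-swipe counts.
#' @param sensor_rate_hz Device-motion sampling rate (0 disables streams).
#' @param effect_map Planted effects, see [default_effect_map()].
#' @param unmatched_id_count Number of trailing participants whose session
#'   logs carry corrupted device ids absent from the questionnaire table
#'   (emulates unlinkable records).
#' @param tap_rate Expected fraction of accidental taps interleaved with
#'   real swipes.
#' @param menu_swipes Menu-navigation swipes logged before gameplay.
#' @param gameplay Low-level signal scales; see source.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_participants = 82, seed = 1, latent_cor = 0.6,
                          games = GAMES,
                          swipes_per_session = c(puzzle = 350, runner = 500,
                                                 slicer = 400),
                          sensor_rate_hz = 50,
                          effect_map = default_effect_map(),
                          unmatched_id_count = 0,
                          tap_rate = 0.02, menu_swipes = 3,
                          gameplay = list()) {
  stopifnot(n_participants >= 1, abs(latent_cor) <= 1,
            all(games %in% GAMES), sensor_rate_hz >= 0,
            unmatched_id_count >= 0, unmatched_id_count <= n_participants)
  if (nrow(effect_map)) {
    stopifnot(all(abs(effect_map$target) < 1),
              all(effect_map$instrument %in% INSTRUMENTS),
              all(effect_map$game %in% GAMES),
              all(effect_map$mechanism %in% PROFILE_PARAMS))
  }
  gp <- utils::modifyList(list(
    speed_base = c(puzzle = 700, runner = 800, slicer = 950),  # px/s
    speed_sd_log = 0.25,        # between-participant spread of log mean speed
    swipe_speed_cv_log = 0.30,  # within-participant per-swipe spread
    length_log_mean = c(puzzle = log(250), runner = log(300), slicer = log(600)),
    length_log_sd = c(puzzle = 0.30, runner = 0.30, slicer = 0.25),
    press_level_base = 0.45, press_level_sd = 0.05,
    press_swipe_sd = 0.03,      # swipe-to-swipe pressure level jitter
    amp_mid = 0.030, amp_start = 0.035,
    end_press_amp_base = 0.040, end_press_amp_log_slope = 0.40,
    press_floor_range = c(0.12, 0.27), press_floor_gamma_scale = 0.04,
    posY_floor_range = c(120, 380),
    motion_amp_base = 0.5, motion_amp_sd_log = 0.30,
    margin = 80, point_jitter = 1.5,
    curvature_sd = c(puzzle = 0.04, runner = 0.04, slicer = 0.12)
  ), gameplay)
  item_model <- list(
    GAD7 = list(a0 = 1.25176, a1 = 0.86329, sigma = 0.8),
    PHQ8 = list(a0 = 0.94090, a1 = 0.69458, sigma = 0.8)
  )
  structure(list(
    n_participants = as.integer(n_participants), seed = as.integer(seed),
    latent_cor = latent_cor, games = games,
    swipes_per_session = swipes_per_session, sensor_rate_hz = sensor_rate_hz,
    session_limit = 900, gameplay_window = c(20, 890),
    effect_map = effect_map,
    unmatched_id_count = as.integer(unmatched_id_count),
    tap_rate = tap_rate, menu_swipes = as.integer(menu_swipes),
    item_model = item_model, gameplay = gp
  ), class = "cohort_config")
}

#' Generate questionnaire item responses from a latent trait
#'
#' Each item rating is a clamped discretization of the trait plus item
#' noise: `clamp(round(a0 + a1 * trait + e), 0, 3)` with `e ~ N(0,
#' sigma)`. Constants come from the config's item model, calibrated so
#' population totals match the emulated sample moments. Uses the current
#' RNG state; seed beforehand for reproducibility.
#'
#' @param latent Numeric vector of standard-normal trait values.
#' @param instrument `"GAD7"` or `"PHQ8"`.
#' @param config A [cohort_config()].
#' @return Integer matrix, one row per trait value, one column per item.
#' @export
generate_item_responses <- function(latent, instrument,
                                    config = cohort_config()) {
  info <- instrument_info(instrument)
  im <- config$item_model[[info$instrument]]
  n <- length(latent)
  items <- matrix(0L, n, info$n_items)
  for (j in seq_len(info$n_items)) {
    y <- im$a0 + im$a1 * latent + stats::rnorm(n, 0, im$sigma)
    items[, j] <- pmin(3L, pmax(0L, as.integer(round(y))))
  }
  colnames(items) <- paste0(tolower(gsub("-?", "", info$instrument)), "_q",
                            seq_len(info$n_items))
  items
}

# Solve trait loadings for one mechanism parameter from the signed
# latent_rho requirements of its effect entries (at most one per
# instrument). Returns c(anx, dep, noise_sd) with unit total variance.
effect_loadings <- function(entries, latent_cor) {
  r <- c(GAD7 = 0, PHQ8 = 0)
  constrained <- c(GAD7 = FALSE, PHQ8 = FALSE)
  for (i in seq_len(nrow(entries))) {
    inst <- entries$instrument[i]
    r[inst] <- sign(entries$target[i]) * entries$latent_rho[i]
    constrained[inst] <- TRUE
  }
  sigma <- matrix(c(1, latent_cor, latent_cor, 1), 2)
  cc <- c(0, 0)
  if (all(constrained)) {
    cc <- solve(sigma, r)
  } else if (constrained["GAD7"]) {
    cc <- c(r[["GAD7"]], 0)
  } else if (constrained["PHQ8"]) {
    cc <- c(0, r[["PHQ8"]])
  }
  expl <- as.numeric(t(cc) %*% sigma %*% cc)
  if (expl >= 1) {
    stop("planted effects for one parameter demand more than unit variance; ",
         "weaken latent_rho", call. = FALSE)
  }
  c(anx = cc[1], dep = cc[2], noise_sd = sqrt(1 - expl))
}

# Draw participant profiles: severity traits plus, for every game, the
# mechanism parameters on their natural scales. Planted parameters load on
# the traits; everything else is pure between-participant noise.
draw_profiles <- function(config, traits) {
  n <- nrow(traits)
  gp <- config$gameplay
  profiles <- list(traits = traits)
  for (game in GAMES) {
    lat <- matrix(stats::rnorm(n * length(PROFILE_PARAMS)), n,
                  dimnames = list(NULL, PROFILE_PARAMS))
    em <- config$effect_map
    em <- em[em$game == game, , drop = FALSE]
    for (param in unique(em$mechanism)) {
      ld <- effect_loadings(em[em$mechanism == param, , drop = FALSE],
                            config$latent_cor)
      lat[, param] <- ld[["anx"]] * traits[, 1] + ld[["dep"]] * traits[, 2] +
        ld[["noise_sd"]] * lat[, param]
    }
    pf <- gp$press_floor_range
    yf <- gp$posY_floor_range
    profiles[[game]] <- data.frame(
      speed = gp$speed_base[[game]] * exp(gp$speed_sd_log * lat[, "speed"]),
      end_press_amp = gp$end_press_amp_base *
        exp(gp$end_press_amp_log_slope * lat[, "end_press_amp"]),
      press_level = gp$press_level_base + gp$press_level_sd * lat[, "press_level"],
      press_floor = pf[1] + diff(pf) * stats::pnorm(lat[, "press_floor"]),
      start_posY_floor = yf[1] + diff(yf) * stats::pnorm(lat[, "start_posY_floor"]),
      motion_amp = gp$motion_amp_base *
        exp(gp$motion_amp_sd_log * lat[, "motion_amp"])
    )
  }
  profiles
}

# Vectorized swipe-metric derivation for one session's path table.
# `paths` rows must be grouped by swipe in `anchors` order. Semantics
# match derive_swipe_metrics() exactly.
derive_all_swipes <- function(paths, anchors, game, config = cleaning_config()) {
  npts <- anchors$npts
  n <- length(npts)
  last <- cumsum(npts)
  first <- c(1L, utils::head(last, -1L) + 1L)
  idx <- rep.int(seq_len(n), npts)
  N <- nrow(paths)

  seg <- sqrt(diff(paths$x)^2 + diff(paths$y)^2)
  within <- idx[-1] == idx[-N]
  dist <- as.vector(rowsum(seg[within], idx[-1][within]))
  dur <- paths$t[last] - paths$t[first]

  p <- paths$press
  psum <- as.vector(rowsum(p, idx))
  psq <- as.vector(rowsum(p * p, idx))
  pmean <- psum / npts
  pvar <- ifelse(npts > 1, pmax(0, (psq - npts * pmean^2) / (npts - 1)), 0)

  pos_in <- sequence(npts)
  k <- pmin(5L, npts)
  head_mask <- pos_in <= k[idx]
  tail_mask <- pos_in > (npts - k)[idx]
  lvar <- function(mask) {
    s1 <- as.vector(rowsum(p[mask], idx[mask]))
    s2 <- as.vector(rowsum(p[mask]^2, idx[mask]))
    m <- s1 / k
    ifelse(k > 1, pmax(0, (s2 - k * m^2) / (k - 1)), 0)
  }
  disp_x <- paths$x[last] - paths$x[first]
  disp_y <- paths$y[last] - paths$y[first]
  disp <- sqrt(disp_x^2 + disp_y^2)
  speed_len <- if (config$speed_mode == "path") dist else disp

  data.frame(
    swipe_id = anchors$swipe_id,
    event_time = anchors$event_time,
    start_time = anchors$start_time,
    end_time = anchors$start_time + dur,
    start_x = paths$x[first], start_y = paths$y[first],
    end_x = paths$x[last], end_y = paths$y[last],
    start_press = p[first], end_press = p[last],
    start_press_variance = lvar(head_mask),
    end_press_variance = lvar(tail_mask),
    press_mean = pmean, press_variance = pvar,
    speed = speed_len / dur, duration = dur, distance = dist,
    direction = if (game == "slicer") rep("none", n) else
      quantize_direction(disp_x, disp_y),
    time_between_swipes = anchors$time_between_swipes,
    stringsAsFactors = FALSE
  )
}

#' Synthesize one game session
#'
#' Samples a full event stream for one participant x game: gameplay swipes
#' (noisy line/arc touch traces with per-point contact-area pressures),
#' menu-navigation swipes before and after the gameplay window, occasional
#' sub-threshold taps, and free-running accelerometer/gyroscope streams.
#' Puzzle and runner swipes are axis-aligned with a quantized direction;
#' slicer swipes are longer arcs with direction `"none"`. All swipe
#' randomness is drawn before sensor randomness, so the swipe stream is
#' invariant to the sensor rate under a fixed seed. Uses the current RNG
#' state; seed beforehand for reproducibility.
#'
#' @param profile One row of a game's profile table (participant-level
#'   parameters, all strictly positive scales).
#' @param game Game archetype.
#' @param config A [cohort_config()].
#' @param participant_id Participant id stamped on the session.
#' @return A `game_session` whose stored metrics are exactly the derived
#'   ones (writer/deriver self-consistency).
#' @export
synthesize_session <- function(profile, game, config = cohort_config(),
                               participant_id = "P000") {
  game <- match.arg(game, GAMES)
  gp <- config$gameplay
  dims <- game_screen_dims(game)
  W <- dims[1]; H <- dims[2]
  win <- config$gameplay_window
  m <- gp$margin

  n <- max(5L, stats::rpois(1, config$swipes_per_session[[game]]))
  sp <- profile$speed * stats::rlnorm(n, 0, gp$swipe_speed_cv_log)
  L <- stats::rlnorm(n, gp$length_log_mean[[game]], gp$length_log_sd[[game]])
  L <- pmax(40, pmin(L, 1500))

  if (game == "slicer") {
    x0 <- stats::runif(n, 120, W - 120)
    y0 <- stats::runif(n, profile$start_posY_floor, H - 150)
    theta <- stats::runif(n, 0, 2 * pi)
    ex <- pmin(W - 10, pmax(10, x0 + L * cos(theta)))
    ey <- pmin(H - 10, pmax(10, y0 + L * sin(theta)))
    Leff <- pmax(30, sqrt((ex - x0)^2 + (ey - y0)^2))
  } else {
    dirs <- sample(DIRECTIONS, n, replace = TRUE)
    horiz <- dirs %in% c("left", "right")
    Leff <- pmin(L, ifelse(horiz, W, H) - 2 * m - 1)
    x0 <- stats::runif(n, m, W - m)
    y0 <- stats::runif(n, m, H - m)
    x0[dirs == "right"] <- stats::runif(sum(dirs == "right"), m,
                                        (W - m - Leff)[dirs == "right"])
    x0[dirs == "left"] <- stats::runif(sum(dirs == "left"),
                                       (m + Leff)[dirs == "left"], W - m)
    y0[dirs == "up"] <- stats::runif(sum(dirs == "up"), m,
                                     (H - m - Leff)[dirs == "up"])
    y0[dirs == "down"] <- stats::runif(sum(dirs == "down"),
                                       (m + Leff)[dirs == "down"], H - m)
    ex <- x0 + Leff * ((dirs == "right") - (dirs == "left"))
    ey <- y0 + Leff * ((dirs == "up") - (dirs == "down"))
  }
  dur <- pmax(0.05, pmin(2.5, Leff / sp))

  gaps_raw <- stats::rgamma(n, shape = 2, rate = 1)
  budget <- diff(win) * stats::runif(1, 0.90, 0.97) - sum(dur)
  gaps <- gaps_raw / sum(gaps_raw) * max(budget, 0.02 * n)
  starts <- win[1] + cumsum(gaps + dur) - dur
  tbs <- gaps
  tbs[1] <- NA_real_

  # touch traces for gameplay swipes
  npts <- pmax(6L, pmin(36L, as.integer(ceiling(dur * 50))))
  idx <- rep.int(seq_len(n), npts)
  f <- (sequence(npts) - 1) / (npts[idx] - 1)
  ux <- (ex - x0) / Leff
  uy <- (ey - y0) / Leff
  curv <- stats::rnorm(n, 0, gp$curvature_sd[[game]])
  arc <- (curv * Leff)[idx] * sin(pi * f)
  px <- x0[idx] + f * (ex - x0)[idx] - arc * uy[idx] +
    stats::rnorm(length(f), 0, gp$point_jitter)
  py <- y0[idx] + f * (ey - y0)[idx] + arc * ux[idx] +
    stats::rnorm(length(f), 0, gp$point_jitter)
  px <- pmin(W, pmax(0, px))
  py <- pmin(H, pmax(0, py))

  lv <- if (game == "slicer") {
    profile$press_floor + stats::rgamma(n, shape = 2,
                                        scale = gp$press_floor_gamma_scale)
  } else {
    profile$press_level + stats::rnorm(n, 0, gp$press_swipe_sd)
  }
  pos_in <- sequence(npts)
  from_end <- npts[idx] - pos_in
  amp <- ifelse(from_end < 5, profile$end_press_amp,
                ifelse(pos_in <= 5, gp$amp_start, gp$amp_mid))
  press <- pmin(0.995, pmax(0.005, lv[idx] + amp * stats::rnorm(length(f))))

  core_paths <- data.frame(swipe_id = idx, t = f * dur[idx],
                           x = px, y = py, press = press)
  core_anchors <- data.frame(swipe_id = seq_len(n), event_time = starts,
                             start_time = starts - win[1],
                             time_between_swipes = tbs, npts = npts)

  extras <- synthesize_stray_touches(n, game, config, W, H)
  paths <- data.frame(
    swipe_id = c(core_paths$swipe_id, extras$paths$swipe_id + n),
    t = c(core_paths$t, extras$paths$t),
    x = c(core_paths$x, extras$paths$x),
    y = c(core_paths$y, extras$paths$y),
    press = c(core_paths$press, extras$paths$press)
  )
  anchors <- data.frame(
    swipe_id = c(core_anchors$swipe_id, extras$anchors$swipe_id + n),
    event_time = c(core_anchors$event_time, extras$anchors$event_time),
    start_time = c(core_anchors$start_time, extras$anchors$start_time),
    time_between_swipes = c(core_anchors$time_between_swipes,
                            extras$anchors$time_between_swipes),
    npts = c(core_anchors$npts, extras$anchors$npts)
  )

  swipes <- derive_all_swipes(paths, anchors, game)
  ord <- order(swipes$event_time)
  swipes <- swipes[ord, , drop = FALSE]
  id_map <- integer(nrow(swipes))
  id_map[swipes$swipe_id] <- seq_len(nrow(swipes))
  paths$swipe_id <- id_map[paths$swipe_id]
  swipes$swipe_id <- seq_len(nrow(swipes))
  rownames(swipes) <- NULL
  paths <- paths[order(paths$swipe_id, paths$t), , drop = FALSE]
  rownames(paths) <- NULL

  sensors <- if (config$sensor_rate_hz > 0) {
    ts <- seq(0, config$session_limit, by = 1 / config$sensor_rate_hz)
    nm <- length(ts)
    ga <- 0.2 * profile$motion_amp
    data.frame(
      stream = rep(c("accelerometer", "gyroscope"), each = nm),
      t = c(ts, ts),
      x = c(stats::rnorm(nm, 0, profile$motion_amp), stats::rnorm(nm, 0, ga)),
      y = c(stats::rnorm(nm, 0, profile$motion_amp), stats::rnorm(nm, 0, ga)),
      z = c(stats::rnorm(nm, 9.81, profile$motion_amp), stats::rnorm(nm, 0, ga)),
      stringsAsFactors = FALSE
    )
  } else empty_sensors()

  game_session(participant_id, game, swipes = swipes, paths = paths,
               sensors = sensors, session_limit = config$session_limit,
               gameplay_window = win)
}

# Menu-navigation swipes outside the gameplay window plus accidental taps
# inside it (both removed by cleaning).
synthesize_stray_touches <- function(n_core, game, config, W, H) {
  win <- config$gameplay_window
  n_menu <- config$menu_swipes
  n_tap <- stats::rpois(1, config$tap_rate * n_core)
  n <- n_menu + 1L + n_tap
  ev <- c(sort(stats::runif(n_menu, 2, win[1] - 2)),
          stats::runif(1, win[2] + 1, config$session_limit - 2),
          sort(stats::runif(n_tap, win[1] + 1, win[2] - 1)))
  is_tap <- c(rep(FALSE, n_menu + 1L), rep(TRUE, n_tap))
  L <- ifelse(is_tap, stats::runif(n, 1, 6), stats::runif(n, 60, 150))
  ang <- ifelse(is_tap, stats::runif(n, 0, 2 * pi),
                sample(c(0, pi / 2, pi, 3 * pi / 2), n, replace = TRUE))
  x0 <- stats::runif(n, 0.3 * W, 0.7 * W)
  y0 <- stats::runif(n, 0.3 * H, 0.7 * H)
  dur <- ifelse(is_tap, 0.04, stats::runif(n, 0.15, 0.4))
  npts <- ifelse(is_tap, 3L, 6L)
  idx <- rep.int(seq_len(n), npts)
  f <- (sequence(npts) - 1) / (npts[idx] - 1)
  paths <- data.frame(
    swipe_id = idx, t = f * dur[idx],
    x = pmin(W, pmax(0, x0[idx] + f * (L * cos(ang))[idx])),
    y = pmin(H, pmax(0, y0[idx] + f * (L * sin(ang))[idx])),
    press = pmin(0.995, pmax(0.005, 0.4 + 0.03 * stats::rnorm(length(f))))
  )
  anchors <- data.frame(swipe_id = seq_len(n), event_time = ev,
                        start_time = ev - win[1],
                        time_between_swipes = NA_real_, npts = npts)
  list(paths = paths, anchors = anchors)
}

#' Generate a complete synthetic cohort
#'
#' Draws participant severity traits, questionnaire responses, and one
#' session per configured game, fully reproducible from the master seed.
#' Sub-seeds are derived per component (traits, questionnaires,
#' demographics, each session), so e.g. restricting `config$games` leaves
#' the questionnaire table byte-identical. When `unmatched_id_count > 0`,
#' the trailing participants' session logs carry corrupted device ids that
#' do not appear in the questionnaire table.
#'
#' @param config A [cohort_config()].
#' @return List: `sessions` (flat list of `game_session`),
#'   `questionnaires` (data frame in the standard CSV layout), `profiles`
#'   (latent traits and per-game parameters).
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_participants
  ids <- sprintf("P%03d", seq_len(n))

  set.seed(config$seed)
  n_session_seeds <- n * length(GAMES)
  seeds <- sample.int(.Machine$integer.max - 1L, 4L + n_session_seeds)
  trait_seed <- seeds[1]; quest_seed <- seeds[2]
  profile_seed <- seeds[3]; demo_seed <- seeds[4]
  session_seeds <- matrix(seeds[-(1:4)], nrow = n,
                          dimnames = list(NULL, GAMES))

  set.seed(trait_seed)
  z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
  rho <- config$latent_cor
  traits <- cbind(anxiety = z1, depression = rho * z1 + sqrt(1 - rho^2) * z2)

  set.seed(quest_seed)
  gad <- generate_item_responses(traits[, "anxiety"], "GAD7", config)
  phq <- generate_item_responses(traits[, "depression"], "PHQ8", config)

  set.seed(demo_seed)
  demo <- data.frame(
    age_band = sample(c("18-20", "21-30", "31-40"), n, replace = TRUE,
                      prob = c(0.50, 0.45, 0.05)),
    sex = sample(c("male", "female"), n, replace = TRUE, prob = c(0.38, 0.62)),
    gamer_identity = sample(c("nongamer", "casual gamer", "gamer"), n,
                            replace = TRUE, prob = c(0.18, 0.65, 0.17)),
    stringsAsFactors = FALSE
  )
  questionnaires <- cbind(data.frame(participant_id = ids,
                                     stringsAsFactors = FALSE),
                          as.data.frame(gad), as.data.frame(phq), demo)

  set.seed(profile_seed)
  profiles <- draw_profiles(config, traits)

  device_ids <- ids
  if (config$unmatched_id_count > 0) {
    k <- config$unmatched_id_count
    corrupt <- seq.int(n - k + 1L, n)
    device_ids[corrupt] <- sprintf("DEV%03d", corrupt)
  }

  sessions <- list()
  for (game in config$games) {
    for (i in seq_len(n)) {
      set.seed(session_seeds[i, game])
      sessions[[length(sessions) + 1L]] <-
        synthesize_session(profiles[[game]][i, , drop = FALSE], game, config,
                           participant_id = device_ids[i])
    }
  }
  list(sessions = sessions, questionnaires = questionnaires,
       profiles = profiles)
}

#' Write a small fixture cohort to disk
#'
#' Bundles a 5-participant cohort with scaled-down sessions in the
#' standard on-disk formats (one JSON log per session plus
#' `questionnaires.csv`), for unit tests and worked examples.
#'
#' @param dir Output directory (created if needed).
#' @param n_participants,seed Cohort size and seed.
#' @param swipes_per_session Poisson means (scaled down by default).
#' @param sensor_rate_hz Sensor rate (scaled down by default).
#' @return The config used, invisibly; files land in `dir`.
#' @export
simulate_fixture_cohort <- function(dir, n_participants = 5, seed = 20,
                                    swipes_per_session = c(puzzle = 40,
                                                           runner = 50,
                                                           slicer = 45),
                                    sensor_rate_hz = 2) {
  config <- cohort_config(n_participants = n_participants, seed = seed,
                          swipes_per_session = swipes_per_session,
                          sensor_rate_hz = sensor_rate_hz)
  cohort <- generate_cohort(config)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in cohort$sessions) {
    write_session_log(s, file.path(dir, sprintf("session_%s_%s.json",
                                                s$participant_id, s$game)))
  }
  write_questionnaire_table(cohort$questionnaires,
                            file.path(dir, "questionnaires.csv"))
  invisible(config)
}

#' Recover planted effects through the full pipeline
#'
#' For each replicate cohort: synthesize sessions, clean, IQR-filter,
#' aggregate into feature vectors, score questionnaires, and compute the
#' Spearman correlation of every planted (feature, instrument) pair.
#' The mean recovered rho across replicates is the quantity the planted
#' targets are calibrated against.
#'
#' Sensor streams are not synthesized during recovery: every planted
#' mechanism acts on swipe parameters, and session seeds draw all swipe
#' randomness before sensor randomness, so the swipe-derived feature
#' values (and hence every recovered rho) are bit-identical with or
#' without the streams.
#'
#' @param config A [cohort_config()]; its `seed` is replaced per
#'   replicate by `seed + replicate index`.
#' @param n_reps Number of replicate cohorts.
#' @param seed Base seed.
#' @param cleaning A [cleaning_config()].
#' @return Data frame (one row per effect entry): `game`, `feature`,
#'   `instrument`, `target`, `mean_rho`, `sd_rho`, `n_reps`; per-replicate
#'   rho values as attribute `"replicates"` (matrix reps x entries).
#' @export
recover_planted_effects <- function(config = cohort_config(n_participants = 78),
                                    n_reps = 100, seed = 500,
                                    cleaning = cleaning_config()) {
  em <- config$effect_map
  stopifnot(nrow(em) > 0)
  config$games <- intersect(GAMES, unique(em$game))
  config$sensor_rate_hz <- 0
  totals <- c(GAD7 = "gad7_total", PHQ8 = "phq8_total")
  rho_mat <- matrix(NA_real_, n_reps, nrow(em))
  for (r in seq_len(n_reps)) {
    cfg <- config
    cfg$seed <- config$seed + seed + r
    cohort <- generate_cohort(cfg)
    scored <- score_questionnaire_table(cohort$questionnaires)
    games_here <- vapply(cohort$sessions, function(s) s$game, character(1))
    for (g in unique(em$game)) {
      feats <- extract_features(cohort$sessions[games_here == g], cleaning)
      merged <- merge(feats, scored[, c("participant_id", "gad7_total",
                                        "phq8_total")], by = "participant_id",
                      sort = FALSE)
      for (j in which(em$game == g)) {
        res <- spearman_cor(merged[[em$feature[j]]],
                            merged[[totals[[em$instrument[j]]]]])
        rho_mat[r, j] <- res$rho
      }
    }
  }
  out <- data.frame(em[, c("game", "feature", "instrument", "target")],
                    mean_rho = colMeans(rho_mat),
                    sd_rho = apply(rho_mat, 2, stats::sd),
                    n_reps = n_reps)
  attr(out, "replicates") <- rho_mat
  out
}

#' Calibrate one planted effect
#'
#' Monte-Carlo search for the trait-parameter coupling `latent_rho` that
#' makes the full pipeline recover `target_spearman` for one effect
#' entry. Evaluates the recovered mean rho on a coarse grid of couplings
#' (each with `n_reps` replicate cohorts, sessions synthesized for the
#' affected game only) and inverts the monotone response curve by linear
#' interpolation. A zero target returns a zero coupling without
#' simulation.
#'
#' @param spec One effect entry: list or one-row data frame with `game`,
#'   `feature`, `instrument`, `target` (and `mechanism`).
#' @param config A [cohort_config()] providing the cohort conditions.
#' @param n_reps Replicates per grid point (>= 50 recommended).
#' @param seed Base seed for the search.
#' @param grid Candidate couplings to probe.
#' @return List: `latent_rho`, `achieved` (interpolated recovered rho),
#'   `grid` (data frame of probed couplings and recovered means).
#' @export
calibrate_effect <- function(spec, config = cohort_config(n_participants = 78),
                             n_reps = 50, seed = 900,
                             grid = c(0.25, 0.40, 0.55, 0.70, 0.85)) {
  spec <- as.list(as.data.frame(spec))
  stopifnot(abs(spec$target) < 1)
  if (spec$target == 0) {
    return(list(latent_rho = 0, achieved = 0,
                grid = data.frame(latent_rho = 0, mean_rho = 0)))
  }
  if (is.null(spec$mechanism)) {
    spec$mechanism <- default_effect_map()$mechanism[
      match(spec$feature, default_effect_map()$feature)]
  }
  cfg <- config
  cfg$games <- spec$game
  cfg$sensor_rate_hz <- 0 # sensors are drawn after swipes: no effect on swipe features
  means <- numeric(length(grid))
  for (i in seq_along(grid)) {
    cfg$effect_map <- data.frame(game = spec$game, feature = spec$feature,
                                 instrument = spec$instrument,
                                 target = spec$target, latent_rho = grid[i],
                                 mechanism = spec$mechanism,
                                 stringsAsFactors = FALSE)
    rec <- recover_planted_effects(cfg, n_reps = n_reps, seed = seed)
    means[i] <- rec$mean_rho[1]
  }
  resp <- abs(means)
  tgt <- abs(spec$target)
  if (tgt > max(resp)) {
    stop(sprintf(
      "target |rho| = %.3f unattainable: response tops out at %.3f (noise floor)",
      tgt, max(resp)), call. = FALSE)
  }
  latent_rho <- stats::approx(resp, grid, xout = tgt, ties = mean)$y
  achieved <- stats::approx(grid, resp, xout = latent_rho, ties = mean)$y
  list(latent_rho = latent_rho, achieved = sign(spec$target) * achieved,
       grid = data.frame(latent_rho = grid, mean_rho = means))
}
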