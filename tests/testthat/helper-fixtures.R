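# Shared fixtures: hand-built sessions, a small generated cohort, and the
# lazily computed heavy simulations reused across test files.

# A session assembled from explicit touch traces (one data.frame per
# swipe), with stored metrics filled in by the metric deriver.
session_from_paths <- function(path_list, game = "puzzle",
                               event_times = seq(30, by = 10,
                                                 length.out = length(path_list)),
                               tbs = rep(NA_real_, length(path_list))) {
  rows <- lapply(seq_along(path_list), function(i) {
    derive_swipe_metrics(path_list[[i]],
                         anchors = list(swipe_id = i,
                                        event_time = event_times[i],
                                        start_time = event_times[i] - 20,
                                        time_between_swipes = tbs[i]),
                         game = game)
  })
  swipes <- do.call(rbind, rows)
  paths <- do.call(rbind, lapply(seq_along(path_list), function(i) {
    cbind(swipe_id = i, path_list[[i]])
  }))
  game_session("PX", game, swipes = swipes, paths = paths)
}

# straight horizontal swipe of given length/duration starting at (x0, y0)
line_path <- function(len, dur = 1, x0 = 100, y0 = 200, press = 0.4,
                      npts = 5) {
  f <- seq(0, 1, length.out = npts)
  data.frame(t = f * dur, x = x0 + f * len, y = rep(y0, npts),
             press = rep(press, npts))
}

small_cohort_config <- function(n = 5, seed = 11, sensor_rate_hz = 2, ...) {
  cohort_config(n_participants = n, seed = seed,
                swipes_per_session = c(puzzle = 40, runner = 50, slicer = 45),
                sensor_rate_hz = sensor_rate_hz, ...)
}

.fixture_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

small_cohort <- function() {
  cached("small_cohort", generate_cohort(small_cohort_config()))
}

# Heavy shared computation for the planted-effect acceptance checks:
# mean recovered Spearman rho per default effect entry over 100 cohorts
# of n = 78 run through the full pipeline.
recovery_results <- function() {
  cached("recovery", recover_planted_effects(
    cohort_config(n_participants = 78), n_reps = 100, seed = 2025))
}

# Questionnaire-total calibration runs: grand mean totals over 100
# seeded cohorts of n = 82 (questionnaire draws are sub-seeded, so game
# synthesis is skipped).
questionnaire_means <- function() {
  cached("qmeans", {
    gad <- phq <- numeric(100)
    for (r in 1:100) {
      cfg <- cohort_config(n_participants = 82, seed = 3000 + r,
                           games = character(0))
      q <- score_questionnaire_table(generate_cohort(cfg)$questionnaires)
      gad[r] <- mean(q$gad7_total)
      phq[r] <- mean(q$phq8_total)
    }
    c(GAD7 = mean(gad), PHQ8 = mean(phq))
  })
}
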