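test_that("cohort generation is byte-reproducible under a fixed seed", {
  cfg <- small_cohort_config(n = 3, seed = 77)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1$questionnaires, c2$questionnaires)
  expect_identical(c1$profiles, c2$profiles)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_session_log(c1$sessions[[5]], f1)
  write_session_log(c2$sessions[[5]], f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("questionnaire draws are independent of which games are synthesized", {
  cfg_full <- small_cohort_config(n = 4, seed = 31)
  cfg_none <- small_cohort_config(n = 4, seed = 31, games = character(0))
  cfg_one <- small_cohort_config(n = 4, seed = 31, games = "puzzle")
  full <- generate_cohort(cfg_full)
  expect_identical(full$questionnaires, generate_cohort(cfg_none)$questionnaires)
  one <- generate_cohort(cfg_one)
  expect_identical(full$questionnaires, one$questionnaires)
  # and the shared game's sessions are identical too (per-session sub-seeds)
  fp <- withr::local_tempfile(); op <- withr::local_tempfile()
  g <- vapply(full$sessions, function(s) s$game, "")
  write_session_log(full$sessions[[which(g == "puzzle")[2]]], fp)
  write_session_log(one$sessions[[2]], op)
  expect_identical(unname(tools::md5sum(fp)), unname(tools::md5sum(op)))
})

test_that("sensor synthesis does not perturb swipe-derived features", {
  cfg_a <- small_cohort_config(n = 2, seed = 41, sensor_rate_hz = 50)
  cfg_b <- small_cohort_config(n = 2, seed = 41, sensor_rate_hz = 0)
  cfg_a$games <- cfg_b$games <- "puzzle"
  fa <- extract_features(generate_cohort(cfg_a)$sessions)
  fb <- extract_features(generate_cohort(cfg_b)$sessions)
  swipe_cols <- setdiff(names(fa), grep("^(acl|gyro)_", names(fa), value = TRUE))
  expect_identical(fa[, swipe_cols], fb[, swipe_cols])
})

test_that("item responses respect clamping and calibrated population moments", {
  set.seed(1)
  lo <- generate_item_responses(rep(-10, 20), "GAD7")
  expect_true(all(lo == 0))
  hi <- generate_item_responses(rep(10, 20), "PHQ8")
  expect_true(all(hi == 3))
  set.seed(2)
  z <- rnorm(5000)
  g <- generate_item_responses(z, "GAD7")
  expect_true(all(g %in% 0:3))
  expect_lt(abs(mean(rowSums(g)) - 9.09), 0.3)
  p <- generate_item_responses(z, "PHQ8")
  expect_lt(abs(mean(rowSums(p)) - 8.24), 0.3)
})

test_that("synthesized sessions honor game archetype contracts", {
  co <- small_cohort()
  g <- vapply(co$sessions, function(s) s$game, "")
  runner <- co$sessions[[which(g == "runner")[1]]]
  expect_identical(runner$orientation, "portrait")
  expect_identical(runner$screen_dims, c(1080, 2400))
  gameplay <- runner$swipes$event_time >= runner$gameplay_window[1] &
    runner$swipes$event_time <= runner$gameplay_window[2] &
    runner$swipes$distance >= 20
  expect_true(all(runner$swipes$direction[gameplay] %in%
                    c("up", "down", "left", "right")))

  slicer <- co$sessions[[which(g == "slicer")[1]]]
  expect_true(all(slicer$swipes$direction == "none"))
  expect_identical(slicer$orientation, "landscape")

  for (s in co$sessions[c(2, 8, 14)]) {
    expect_true(all(s$paths$x >= 0 & s$paths$x <= s$screen_dims[1]))
    expect_true(all(s$paths$y >= 0 & s$paths$y <= s$screen_dims[2]))
    expect_true(all(s$swipes$event_time <= s$session_limit))
    expect_length(validate_session(s), 0)
  }

  # slicer swipes are longer on average than puzzle swipes
  puzzle <- co$sessions[[which(g == "puzzle")[1]]]
  expect_gt(mean(clean_swipes(slicer)$swipes$distance),
            mean(clean_swipes(puzzle)$swipes$distance))
})

test_that("profiles keep scale parameters strictly positive", {
  co <- small_cohort()
  for (g in c("puzzle", "runner", "slicer")) {
    pf <- co$profiles[[g]]
    expect_true(all(pf$speed > 0))
    expect_true(all(pf$end_press_amp > 0))
    expect_true(all(pf$press_floor > 0 & pf$press_floor < 1))
    expect_true(all(pf$motion_amp > 0))
  }
})

test_that("a null effect map leaves the pipeline at its nominal type-I rate", {
  cfg <- cohort_config(n_participants = 78, seed = 0,
                       games = "runner",
                       swipes_per_session = c(puzzle = 40, runner = 50,
                                              slicer = 45),
                       sensor_rate_hz = 0,
                       effect_map = default_effect_map()[0, ])
  n_reps <- 40
  hits <- 0L; tests <- 0L
  for (r in seq_len(n_reps)) {
    cfg$seed <- 7000 + r
    co <- generate_cohort(cfg)
    feats <- extract_features(co$sessions)
    scored <- score_questionnaire_table(co$questionnaires)
    res <- screen_features(feats, scored,
                           retained = build_catalog("runner")$feature_name)
    all_tests <- attr(res, "all_tests")
    hits <- hits + sum(all_tests$p_value < 0.05)
    tests <- tests + nrow(all_tests)
  }
  rate <- hits / tests
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
})

test_that("planted-effect recovery strengthens monotonically with coupling", {
  base <- cohort_config(n_participants = 60, seed = 5,
                        swipes_per_session = c(puzzle = 60, runner = 60,
                                               slicer = 60),
                        sensor_rate_hz = 0)
  rec_for <- function(rho) {
    em <- data.frame(game = "puzzle", feature = "swipe_speed_mean",
                     instrument = "PHQ8", target = -0.4, latent_rho = rho,
                     mechanism = "speed", stringsAsFactors = FALSE)
    cfg <- base; cfg$effect_map <- em
    recover_planted_effects(cfg, n_reps = 12, seed = 600)$mean_rho
  }
  weak <- rec_for(0.15)
  strong <- rec_for(0.85)
  expect_lt(strong, weak) # negative effect: stronger coupling, lower rho
  expect_lt(strong, -0.5)
  expect_gt(weak, -0.35)
})

test_that("calibrate_effect handles the trivial and impossible targets", {
  z <- calibrate_effect(list(game = "puzzle", feature = "swipe_speed_mean",
                             instrument = "PHQ8", target = 0,
                             mechanism = "speed"))
  expect_equal(z$latent_rho, 0)
  cfg <- cohort_config(n_participants = 30, seed = 1,
                       swipes_per_session = c(puzzle = 30, runner = 30,
                                              slicer = 30))
  expect_error(
    calibrate_effect(list(game = "puzzle", feature = "swipe_speed_mean",
                          instrument = "PHQ8", target = 0.999,
                          mechanism = "speed"),
                     config = cfg, n_reps = 3, grid = c(0.2, 0.5)),
    "unattainable")
})
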