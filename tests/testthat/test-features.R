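test_that("derived kinematics match closed-form values", {
  # 3-4-5 triangle hypotenuse
  p <- data.frame(t = c(0, 0.5), x = c(0, 3), y = c(0, 4),
                  press = c(0.4, 0.4))
  m <- derive_swipe_metrics(p, list(swipe_id = 1, event_time = 30,
                                    start_time = 10), "puzzle")
  expect_equal(m$distance, 5)
  expect_equal(m$speed, 10)
  expect_equal(m$duration, 0.5)
  expect_equal(m$direction, "up")

  # segment sum: (0,0)->(3,0)->(3,4) over 1 s
  p2 <- data.frame(t = c(0, 0.4, 1), x = c(0, 3, 3), y = c(0, 0, 4),
                   press = c(0.4, 0.4, 0.4))
  m2 <- derive_swipe_metrics(p2, list(swipe_id = 1, event_time = 30,
                                      start_time = 10), "slicer")
  expect_equal(m2$distance, 7)
  expect_equal(m2$speed, 7)
  expect_equal(m2$direction, "none")
  expect_equal(m2$press_mean, 0.4)
  expect_equal(m2$press_variance, 0)

  # displacement mode divides net displacement (5) by duration
  m3 <- derive_swipe_metrics(p2, list(swipe_id = 1, event_time = 30,
                                      start_time = 10), "slicer",
                             cleaning_config(speed_mode = "displacement"))
  expect_equal(m3$speed, 5)

  expect_error(derive_swipe_metrics(p[1, ], list(swipe_id = 1, event_time = 0,
                                                 start_time = 0), "puzzle"),
               "tap")
})

test_that("direction quantization uses the dominant axis with horizontal ties", {
  expect_identical(quantize_direction(10, 2), "right")
  expect_identical(quantize_direction(0, -8), "down")
  expect_identical(quantize_direction(5, 5), "right")
  expect_identical(quantize_direction(-5, 5), "left")
  expect_identical(quantize_direction(-1, -9), "down")
  expect_error(quantize_direction(0, 0), "zero displacement")
})

test_that("cleaning drops menu swipes and sub-threshold touches only", {
  paths <- c(replicate(10, line_path(100), simplify = FALSE),
             list(line_path(2, npts = 3)))  # a tap
  ev <- c(5, 12, seq(30, 100, length.out = 8), 50) # first two before window
  s <- session_from_paths(paths, event_times = ev)
  cleaned <- clean_swipes(s)
  expect_equal(nrow(cleaned$swipes), 8)
  expect_equal(attr(cleaned, "removal_log"),
               c(menu = 2L, sub_threshold = 1L))
  expect_true(all(cleaned$paths$swipe_id %in% cleaned$swipes$swipe_id))

  all_ok <- session_from_paths(replicate(3, line_path(80), simplify = FALSE))
  cleaned2 <- clean_swipes(all_ok)
  expect_equal(cleaned2$swipes, all_ok$swipes)
  expect_equal(attr(cleaned2, "removal_log"), c(menu = 0L, sub_threshold = 0L))
})

test_that("the Tukey fence removes the planted outlier and nothing else", {
  # Q1 = 3.25, Q3 = 7.75 by linear interpolation; fences [-3.5, 14.5]
  v <- c(1:9, 100)
  f <- iqr_filter(v, 1.5)
  expect_equal(f$values, 1:9)
  expect_equal(which(f$outlier), 10L)

  same <- iqr_filter(rep(7, 10))
  expect_equal(same$values, rep(7, 10))
  expect_false(any(same$outlier))

  expect_equal(iqr_filter(c(5, 1, 900))$values, c(5, 1, 900)) # n < 4 passthrough
})

test_that("iqr_filter returns an ordered subsequence, deterministically", {
  set.seed(7)
  for (i in 1:20) {
    v <- stats::rlnorm(50, 0, 1)
    f1 <- iqr_filter(v)
    f2 <- iqr_filter(v)
    expect_identical(f1, f2)
    expect_identical(f1$values, v[!f1$outlier])
    expect_true(all(f1$values %in% v))
  }
})

test_that("catalogs enumerate the expected feature space", {
  for (g in c("puzzle", "runner", "slicer")) {
    cat_df <- build_catalog(g)
    expect_gte(nrow(cat_df), 140)
    expect_lte(nrow(cat_df), 160)
    expect_false(anyDuplicated(cat_df$feature_name) > 0)
    expect_identical(cat_df$feature_name,
                     paste0(cat_df$base, "_", cat_df$aggregator))
  }
  expect_true("swipe_press_variance_std" %in% build_catalog("puzzle")$feature_name)
  expect_true("swipe_count" %in% build_catalog("runner")$feature_name)
  expect_false(any(grepl("count_(up|down|left|right)",
                         build_catalog("slicer")$feature_name)))
  expect_true(all(paste0("swipe_count_", c("up", "down", "left", "right"))
                  %in% build_catalog("runner")$feature_name))
  expect_error(build_catalog("chess"))
})

test_that("aggregation reproduces the eight statistics on known speeds", {
  # three swipes with speeds 2, 4, 6 px/s (lengths 30/60/90 over 15 s)
  paths <- list(line_path(30, dur = 15), line_path(60, dur = 15),
                line_path(90, dur = 15))
  s <- session_from_paths(paths)
  v <- aggregate_session(s)
  expect_equal(v[["swipe_speed_mean"]], 4)
  expect_equal(v[["swipe_speed_median"]], 4)
  expect_equal(v[["swipe_speed_min"]], 2)
  expect_equal(v[["swipe_speed_max"]], 6)
  expect_equal(v[["swipe_speed_range"]], 4)
  expect_equal(v[["swipe_speed_first"]], 2)
  expect_equal(v[["swipe_speed_last"]], 6)
  expect_equal(v[["swipe_speed_std"]], 2)
  expect_equal(v[["swipe_count"]], 3)
  expect_equal(v[["swipe_count_right"]], 3)
  expect_equal(v[["swipe_count_up"]], 0)
})

test_that("swipe-free and constant-sensor sessions aggregate to the contract", {
  s <- game_session("P0", "puzzle")
  s$sensors <- data.frame(stream = rep("accelerometer", 10), t = 1:10,
                          x = rep(0.1, 10), y = rep(0.2, 10), z = rep(9.8, 10),
                          stringsAsFactors = FALSE)
  v <- aggregate_session(s)
  expect_equal(v[["swipe_count"]], 0)
  expect_true(all(is.na(v[grep("^swipe_speed", names(v))])))
  expect_equal(v[["acl_X_std"]], 0)
  expect_equal(v[["acl_X_range"]], 0)
  expect_equal(v[["acl_X_mean"]], 0.1)
  expect_error(aggregate_session(s, build_catalog("slicer")), "does not match")
})

test_that("aggregation identities hold on generated sessions", {
  s <- clean_swipes(small_cohort()$sessions[[4]])
  v <- aggregate_session(s)
  for (base in c("swipe_speed", "swipe_duration", "swipe_press",
                 "swipe_end_press_variance", "time_between_swipes")) {
    g <- function(a) v[[paste0(base, "_", a)]]
    expect_lte(g("min"), g("median"))
    expect_lte(g("median"), g("max"))
    expect_equal(g("range"), g("max") - g("min"))
    expect_gte(g("std"), 0)
    if (paste0(base, "_first") %in% names(v)) {
      seqs <- swipesense:::base_sequences(s)[[base]]
      expect_true(g("first") %in% seqs)
      expect_true(g("last") %in% seqs)
    }
  }
})

test_that("extraction is invariant to swipe storage order", {
  s <- small_cohort()$sessions[[7]]
  catalog <- build_catalog(s$game)
  v1 <- aggregate_session(clean_swipes(s), catalog)
  set.seed(99)
  perm <- sample(nrow(s$swipes))
  s$swipes <- s$swipes[perm, , drop = FALSE]
  s$paths <- s$paths[order(match(s$paths$swipe_id, s$swipes$swipe_id), s$paths$t), ,
                     drop = FALSE]
  v2 <- aggregate_session(clean_swipes(s), catalog)
  expect_identical(v1, v2)
})

test_that("stored swipe metrics re-derive from their traces", {
  s <- small_cohort()$sessions[[9]]
  f <- withr::local_tempfile(fileext = ".json")
  write_session_log(s, f)
  r <- read_session_log(f)
  for (i in seq_len(min(10, nrow(r$swipes)))) {
    sw <- r$swipes[i, ]
    p <- r$paths[r$paths$swipe_id == sw$swipe_id, c("t", "x", "y", "press")]
    m <- derive_swipe_metrics(p, list(swipe_id = sw$swipe_id,
                                      event_time = sw$event_time,
                                      start_time = sw$start_time,
                                      time_between_swipes = sw$time_between_swipes),
                              r$game)
    for (col in setdiff(names(sw), c("direction", "time_between_swipes"))) {
      expect_equal(m[[col]], sw[[col]], tolerance = 1e-6)
    }
    expect_identical(m$direction, sw$direction)
  }
})

test_that("pooled-metric IQR scope masks cross-participant outliers", {
  co <- small_cohort()
  g <- vapply(co$sessions, function(s) s$game, "")
  sess <- co$sessions[g == "puzzle"]
  fe <- extract_features(sess, cleaning_config(iqr_scope = "pooled_metric"))
  expect_equal(nrow(fe), length(sess))
  expect_error(extract_features(co$sessions), "single game")
})
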