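# Independent brute-force oracle: mid-ranks computed by definition
# (count of smaller values plus half-correction for ties), rho as the
# explicit Pearson formula, exact p by recursive permutation enumeration.
oracle_midrank <- function(v) {
  vapply(v, function(a) sum(v < a) + (sum(v == a) + 1) / 2, numeric(1))
}
oracle_rho <- function(x, y) {
  rx <- oracle_midrank(x); ry <- oracle_midrank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}
oracle_perms <- function(n) {
  if (n == 1) return(list(1L))
  sub <- oracle_perms(n - 1L)
  out <- list()
  for (p in sub) for (i in seq_len(n)) {
    out[[length(out) + 1L]] <- append(p, n, after = i - 1L)
  }
  out
}
oracle_exact_p <- function(x, y) {
  obs <- abs(oracle_rho(x, y))
  rhos <- vapply(oracle_perms(length(x)), function(p) oracle_rho(x[p], y),
                 numeric(1))
  mean(abs(rhos) >= obs - 1e-12)
}

test_that("spearman matches monotone expectations and the mid-rank oracle", {
  expect_equal(spearman_cor(c(1, 2, 3), c(2, 4, 9))$rho, 1)
  expect_equal(spearman_cor(c(1, 2, 3), c(9, 4, 2))$rho, -1)

  x <- c(1, 2, 2, 4); y <- c(3, 1, 4, 2)
  res <- spearman_cor(x, y)
  expect_equal(res$rho, oracle_rho(x, y), tolerance = 1e-12)
  expect_equal(res$p_value, oracle_exact_p(x, y), tolerance = 1e-12)

  set.seed(5)
  for (i in 1:5) {
    x <- sample(1:4, 7, replace = TRUE)
    y <- sample(1:5, 7, replace = TRUE)
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    res <- spearman_cor(x, y)
    expect_equal(res$rho, oracle_rho(x, y), tolerance = 1e-12)
    expect_equal(res$p_value, oracle_exact_p(x, y), tolerance = 1e-12)
  }
})

test_that("spearman agrees with the reference implementation", {
  set.seed(8)
  # untied small sample: exact p; cor.test is exact and tie-free here
  x <- sample(1:8); y <- sample(1:8)
  ours <- spearman_cor(x, y)
  ref <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  expect_equal(ours$rho, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)

  # large sample: t approximation
  x2 <- rnorm(78); y2 <- 0.4 * x2 + rnorm(78)
  ours2 <- spearman_cor(x2, y2)
  ref2 <- suppressWarnings(stats::cor.test(x2, y2, method = "spearman"))
  expect_equal(ours2$rho, unname(ref2$estimate), tolerance = 1e-12)
  t_ref <- ours2$rho * sqrt(76 / (1 - ours2$rho^2))
  expect_equal(ours2$p_value, 2 * stats::pt(-abs(t_ref), 76), tolerance = 1e-12)
})

test_that("spearman is symmetric and invariant to increasing transforms", {
  set.seed(13)
  x <- rlnorm(40); y <- rnorm(40)
  base <- spearman_cor(x, y)
  expect_equal(spearman_cor(y, x)$rho, base$rho, tolerance = 1e-12)
  expect_equal(spearman_cor(log(x), y)$rho, base$rho, tolerance = 1e-12)
  expect_equal(spearman_cor(3 * x + 7, y)$rho, base$rho, tolerance = 1e-12)
  expect_equal(spearman_cor(x, exp(y))$rho, base$rho, tolerance = 1e-12)
})

test_that("degenerate spearman inputs signal rather than report", {
  expect_error(spearman_cor(1:5, 1:4), "lengths differ")
  expect_error(spearman_cor(c(1, 2), c(3, 4)), ">= 3")
  res <- spearman_cor(rep(1, 10), rnorm(10))
  expect_true(is.na(res$rho) && is.na(res$p_value))
  # missing pairs are dropped before testing
  expect_equal(spearman_cor(c(1, 2, 3, NA), c(2, 4, 9, 1))$n, 3)
})

test_that("pearson matrix flags exact collinearity and independence", {
  set.seed(31)
  f1 <- rnorm(60)
  m <- data.frame(participant_id = as.character(1:60), game = "puzzle",
                  f1 = f1, f2 = 2 * f1, f3 = -f1, f4 = rnorm(60))
  r <- pearson_matrix(m)
  expect_equal(r["f1", "f2"], 1)
  expect_equal(r["f1", "f3"], -1)
  expect_equal(unname(diag(r)), rep(1, 4))
  expect_equal(r, t(r))

  big <- data.frame(participant_id = as.character(1:500),
                    a = rnorm(500), b = rnorm(500))
  expect_lt(abs(pearson_matrix(big)["a", "b"]), 0.2)

  cst <- data.frame(participant_id = as.character(1:10), a = rnorm(10),
                    b = rep(1, 10))
  rc <- pearson_matrix(cst)
  expect_true(is.na(rc["a", "b"]))
  expect_true(attr(rc, "undefined")["a", "b"])
  expect_error(pearson_matrix(m[1:2, ]), ">= 3")
})

test_that("collinear groups reduce to one representative by priority", {
  set.seed(17)
  base <- rnorm(50)
  m <- data.frame(
    participant_id = as.character(1:50),
    swipe_distance_mean = base + rnorm(50, 0, 0.01),
    swipe_speed_mean = base + rnorm(50, 0, 0.01),
    swipe_press_std = rnorm(50)
  )
  kept <- prune_collinear(m)
  expect_true("swipe_speed_mean" %in% kept)
  expect_false("swipe_distance_mean" %in% kept)
  expect_true("swipe_press_std" %in% kept)
  log <- attr(kept, "pruning_log")
  expect_equal(log$dropped_feature, "swipe_distance_mean")
  expect_equal(log$representative, "swipe_speed_mean")

  # below threshold: both retained
  ab <- MASS::mvrnorm(400, c(0, 0), matrix(c(1, 0.85, 0.85, 1), 2),
                      empirical = TRUE)
  m2 <- data.frame(participant_id = as.character(1:400), a = ab[, 1], b = ab[, 2])
  expect_setequal(prune_collinear(m2), c("a", "b"))
})

test_that("pruning is idempotent and leaves no collinear pair", {
  set.seed(23)
  n <- 60
  base1 <- rnorm(n); base2 <- rnorm(n)
  m <- data.frame(participant_id = as.character(1:n))
  for (i in 1:6) m[[paste0("g1_", i)]] <- base1 + rnorm(n, 0, 0.02)
  for (i in 1:4) m[[paste0("g2_", i)]] <- base2 + rnorm(n, 0, 0.02)
  m$solo <- rnorm(n)
  kept <- prune_collinear(m)
  r <- pearson_matrix(m[, c("participant_id", kept)])
  off <- abs(r[upper.tri(r)])
  expect_true(all(off < 0.90, na.rm = TRUE))
  kept2 <- prune_collinear(m[, c("participant_id", kept)])
  expect_identical(as.character(kept2), as.character(kept))
  expect_equal(nrow(attr(kept2, "pruning_log")), 0)
})

test_that("screening reports significant associations in deterministic order", {
  co <- small_cohort()
  scored <- score_questionnaire_table(co$questionnaires)
  n <- nrow(scored)
  set.seed(3)
  feats <- data.frame(participant_id = scored$participant_id,
                      game = "puzzle",
                      mirror = scored$gad7_total + 0.001 * rnorm(n),
                      noise = rnorm(n))
  res <- screen_features(feats, scored, screen_config())
  hit <- res[res$feature_name == "mirror" & res$instrument == "GAD7", ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$rho, 1)
  expect_lt(hit$p_value, 0.05)
  expect_equal(hit$n, n)

  all_tests <- attr(res, "all_tests")
  expect_true(all(res$p_value < 0.05))
  expect_identical(res$instrument, sort(res$instrument))
  expect_gt(nrow(all_tests), nrow(res) - 1)

  empty <- screen_features(feats, scored, retained = character())
  expect_equal(nrow(empty), 0)
})

test_that("the screen's false-positive rate is calibrated at alpha = 0.05", {
  set.seed(271)
  n <- 78
  n_reps <- 1000
  k_feats <- 5
  cfg <- cohort_config(n_participants = n, games = character(0),
                       effect_map = default_effect_map()[0, ])
  hits <- 0L; tests <- 0L
  for (r in seq_len(n_reps)) {
    cfg$seed <- 50000 + r
    q <- score_questionnaire_table(generate_cohort(cfg)$questionnaires)
    feats <- matrix(rnorm(n * k_feats), n)
    for (j in seq_len(k_feats)) {
      for (tot in list(q$gad7_total, q$phq8_total)) {
        p <- spearman_cor(feats[, j], tot)$p_value
        hits <- hits + (p < 0.05)
        tests <- tests + 1L
      }
    }
  }
  rate <- hits / tests
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
})

test_that("reports render deterministically with and without rows", {
  res <- data.frame(feature_name = c("swipe_speed_mean", "swipe_press_min"),
                    instrument = c("PHQ8", "GAD7"),
                    rho = c(-0.405, 0.43), p_value = c(0.001, 0.002),
                    n = c(78L, 78L))
  f <- withr::local_tempfile(fileext = ".csv")
  write_report(res, f)
  out <- utils::read.csv(f)
  expect_equal(nrow(out), 2)
  expect_true(file.exists(paste0(f, ".txt")))
  md5_a <- tools::md5sum(f)
  write_report(res, f)
  expect_identical(tools::md5sum(f), md5_a)

  f2 <- withr::local_tempfile(fileext = ".csv")
  write_report(res[0, ], f2)
  expect_equal(nrow(utils::read.csv(f2)), 0)
})
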