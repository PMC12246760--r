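#' Screening configuration
#'
#' @param collinearity_threshold Absolute Pearson r above which two
#'   features are treated as duplicates (default 0.90).
#' @param alpha Significance level for the screen (default 0.05).
#' @param correction `"none"` (default, uncorrected p values for an
#'   exploratory screen) or `"BH"` (Benjamini-Hochberg within instrument).
#' @param retention_priority Ordered character vector of regular
#'   expressions; when a collinear group must be reduced to one
#'   representative, the feature matching the earliest pattern wins
#'   (lexicographic tie-break). The default prefers speed over
#'   distance/duration and SD-type pressure summaries over raw levels.
#' @return A `screen_config` list.
#' @export
screen_config <- function(collinearity_threshold = 0.90, alpha = 0.05,
                          correction = c("none", "BH"),
                          retention_priority = c(
                            "swipe_speed", "press.*_std$", "press_variance",
                            "pos[XY]", "press", "distance|duration|time_between"
                          )) {
  stopifnot(collinearity_threshold > 0, collinearity_threshold <= 1,
            alpha > 0, alpha < 1)
  structure(list(
    collinearity_threshold = collinearity_threshold, alpha = alpha,
    correction = match.arg(correction),
    retention_priority = retention_priority
  ), class = "screen_config")
}

#' Pairwise Pearson correlation of a feature matrix
#'
#' Pairwise-complete observations; entries for constant features (zero
#' variance) are `NA` and flagged via the `"undefined"` attribute.
#'
#' @param features Feature matrix data frame from [extract_features()]
#'   (non-numeric id columns are ignored) or a plain numeric matrix.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
pearson_matrix <- function(features) {
  m <- feature_values(features)
  if (nrow(m) < 3) stop("need >= 3 participants for a correlation matrix",
                        call. = FALSE)
  r <- suppressWarnings(stats::cor(m, use = "pairwise.complete.obs",
                                   method = "pearson"))
  diag(r) <- 1
  attr(r, "undefined") <- is.na(r)
  r
}

feature_values <- function(features) {
  if (is.matrix(features)) return(features)
  keep <- !(names(features) %in% c("participant_id", "game"))
  as.matrix(features[, keep, drop = FALSE])
}

#' Prune collinear features
#'
#' Features linked by `|r| >= collinearity_threshold` (pairwise-complete
#' Pearson) are grouped into connected components; each group is reduced
#' to a single representative chosen by the configured retention
#' priority, with a lexicographic tie-break. No retained pair is
#' collinear, and pruning an already pruned set changes nothing.
#'
#' @param features Feature matrix (see [pearson_matrix()]).
#' @param config A [screen_config()].
#' @return Character vector of retained feature names, with attribute
#'   `"pruning_log"` (data frame: `dropped_feature`, `representative`,
#'   `r` -- the correlation linking the dropped feature into its group).
#' @export
prune_collinear <- function(features, config = screen_config()) {
  r <- pearson_matrix(features)
  nm <- colnames(r)
  n <- length(nm)
  adj <- !is.na(r) & abs(r) >= config$collinearity_threshold
  diag(adj) <- FALSE

  # connected components by breadth-first search
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cur <- cur + 1L
    queue <- i
    comp[i] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(adj[v, ] & is.na(comp))
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }

  priority <- function(name) {
    hits <- which(vapply(config$retention_priority,
                         function(p) grepl(p, name), logical(1)))
    if (length(hits)) min(hits) else length(config$retention_priority) + 1L
  }
  retained <- character()
  drops <- list()
  for (g in seq_len(cur)) {
    members <- nm[comp == g]
    if (length(members) == 1) {
      retained <- c(retained, members)
      next
    }
    pr <- vapply(members, priority, numeric(1))
    rep_name <- members[order(pr, members)][1]
    retained <- c(retained, rep_name)
    dropped <- setdiff(members, rep_name)
    drops[[length(drops) + 1L]] <- data.frame(
      dropped_feature = dropped, representative = rep_name,
      r = r[dropped, rep_name], stringsAsFactors = FALSE
    )
  }
  retained <- nm[nm %in% retained] # catalog order
  log <- if (length(drops)) do.call(rbind, drops) else
    data.frame(dropped_feature = character(), representative = character(),
               r = numeric())
  rownames(log) <- NULL
  attr(retained, "pruning_log") <- log
  retained
}

# all permutations of 1..n, cached (used for the exact Spearman null)
.perm_cache <- new.env(parent = emptyenv())
all_perms <- function(n) {
  key <- as.character(n)
  if (!is.null(.perm_cache[[key]])) return(.perm_cache[[key]])
  p <- matrix(1L, 1, 1)
  if (n > 1) {
    for (k in 2:n) {
      m <- nrow(p)
      p <- do.call(rbind, lapply(seq_len(k), function(i) {
        cbind(rep(i, m), p + (p >= i))
      }))
    }
  }
  .perm_cache[[key]] <- p
  p
}

#' Spearman rank correlation with exact small-sample p value
#'
#' rho is the Pearson correlation of mid-ranks (average ranks for ties).
#' The two-sided p value uses exact enumeration of all permutations for
#' n <= 9 and otherwise the t approximation with n - 2 degrees of
#' freedom. Pairs with a missing value in either variable are dropped
#' first. A constant input yields an undefined result (`rho = NA`) rather
#' than an error, so callers can exclude it from reports.
#'
#' @param x,y Numeric vectors of equal length.
#' @return List: `rho`, `p_value`, `n` (complete pairs used).
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  ok <- !(is.na(x) | is.na(y))
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need >= 3 complete pairs", call. = FALSE)
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    return(list(rho = NA_real_, p_value = NA_real_, n = n))
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= 9) {
    perms <- all_perms(n)
    # rho is linear in sum(rx[perm] * ry); enumerate that sum
    s_obs <- sum(rx * ry)
    s_all <- as.vector(matrix(rx[perms], nrow = nrow(perms)) %*% ry)
    mu <- n * mean(rx) * mean(ry)
    denom <- (n - 1) * stats::sd(rx) * stats::sd(ry)
    rho_all <- (s_all - mu) / denom
    p <- mean(abs(rho_all) >= abs(rho) - 1e-12)
  } else {
    t_stat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(t_stat), df = n - 2)
  }
  list(rho = rho, p_value = min(p, 1), n = n)
}

#' Screen features against questionnaire totals
#'
#' Computes the Spearman correlation of every retained feature against the
#' GAD-7 and PHQ-8 totals and reports the associations with `p <
#' alpha` (uncorrected by default, mirroring an exploratory screen),
#' sorted by instrument and then catalog order.
#'
#' @param features Feature matrix for one game ([extract_features()]).
#' @param scored Scored questionnaire table
#'   ([score_questionnaire_table()]) with `participant_id`, `gad7_total`,
#'   `phq8_total`.
#' @param config A [screen_config()].
#' @param retained Optional character vector of feature names to test;
#'   defaults to [prune_collinear()] on `features`.
#' @return Data frame of results: `feature_name`, `instrument`, `rho`,
#'   `p_value`, `n`, with the full (unfiltered) test table as attribute
#'   `"all_tests"` and the pruning log as attribute `"pruning_log"`.
#' @export
screen_features <- function(features, scored, config = screen_config(),
                            retained = NULL) {
  stopifnot(all(c("participant_id", "gad7_total", "phq8_total") %in% names(scored)))
  merged <- merge(features, scored[, c("participant_id", "gad7_total", "phq8_total")],
                  by = "participant_id", sort = FALSE)
  if (nrow(merged) < 3) stop("fewer than 3 linked participants", call. = FALSE)
  if (is.null(retained)) {
    retained <- prune_collinear(features[features$participant_id %in%
                                           merged$participant_id, , drop = FALSE],
                                config)
  }
  totals <- c(GAD7 = "gad7_total", PHQ8 = "phq8_total")
  rows <- list()
  for (inst in INSTRUMENTS) {
    tot <- merged[[totals[[inst]]]]
    for (f in retained) {
      v <- merged[[f]]
      ok <- !(is.na(v) | is.na(tot))
      if (sum(ok) < 3) next
      res <- spearman_cor(v, tot)
      if (is.na(res$rho)) next # constant feature: undefined, excluded
      rows[[length(rows) + 1L]] <- data.frame(
        feature_name = f, instrument = inst, rho = res$rho,
        p_value = res$p_value, n = res$n, stringsAsFactors = FALSE
      )
    }
  }
  all_tests <- if (length(rows)) do.call(rbind, rows) else
    data.frame(feature_name = character(), instrument = character(),
               rho = numeric(), p_value = numeric(), n = integer())
  if (config$correction == "BH" && nrow(all_tests)) {
    all_tests$p_value <- stats::ave(all_tests$p_value, all_tests$instrument,
                                    FUN = function(p) stats::p.adjust(p, "BH"))
  }
  sig <- all_tests[all_tests$p_value < config$alpha, , drop = FALSE]
  rownames(sig) <- NULL
  attr(sig, "all_tests") <- all_tests
  attr(sig, "pruning_log") <- attr(retained, "pruning_log")
  sig
}

#' Write a correlation screen report
#'
#' Emits the results as CSV plus a human-readable text table grouped by
#' instrument (columns: metric, rho, p value). Ordering is deterministic.
#'
#' @param results Data frame from [screen_features()].
#' @param path Output path for the CSV; the text table goes to
#'   `<path>.txt`.
#' @export
write_report <- function(results, path) {
  res <- results[, c("feature_name", "instrument", "rho", "p_value", "n"),
                 drop = FALSE]
  utils::write.csv(res, path, row.names = FALSE)
  txt <- character()
  for (inst in unique(res$instrument)) {
    block <- res[res$instrument == inst, , drop = FALSE]
    txt <- c(txt, sprintf("== %s ==", inst),
             sprintf("%-38s %8s %8s", "Metric", "rho", "P"),
             sprintf("%-38s %8.3f %8.3g", block$feature_name, block$rho,
                     block$p_value),
             "")
  }
  writeLines(txt, paste0(path, ".txt"))
  invisible(path)
}
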