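#' Pipeline run configuration
#'
#' Bundles every stage's settings into one flat, auditable object. Can be
#' written to / read from YAML so a run is fully described by one file
#' plus a seed.
#'
#' @param out_dir Output directory for stage artifacts.
#' @param seed Master seed (forwarded into the cohort config).
#' @param cohort A [cohort_config()] (used by the simulate stage).
#' @param cleaning A [cleaning_config()].
#' @param screen A [screen_config()].
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir, seed = 1, cohort = cohort_config(seed = seed),
                       cleaning = cleaning_config(), screen = screen_config()) {
  cohort$seed <- as.integer(seed)
  structure(list(out_dir = out_dir, seed = as.integer(seed), cohort = cohort,
                 cleaning = cleaning, screen = screen),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  cohort_args <- y$cohort %||% list()
  if (!is.null(cohort_args$effect_map)) {
    cohort_args$effect_map <- as.data.frame(
      do.call(rbind, lapply(cohort_args$effect_map, as.data.frame)))
  }
  if (!is.null(cohort_args$swipes_per_session)) {
    cohort_args$swipes_per_session <- unlist(cohort_args$swipes_per_session)
  }
  run_config(
    out_dir = y$out_dir %||% ".",
    seed = y$seed %||% 1,
    cohort = do.call(cohort_config, cohort_args),
    cleaning = do.call(cleaning_config, y$cleaning %||% list()),
    screen = do.call(screen_config, y$screen %||% list())
  )
}

stage_paths <- function(out_dir) {
  list(
    data_dir = file.path(out_dir, "data"),
    questionnaires = file.path(out_dir, "data", "questionnaires.csv"),
    scored = file.path(out_dir, "questionnaires_scored.csv"),
    features = function(g) file.path(out_dir, sprintf("features_%s.csv", g)),
    results = function(g) file.path(out_dir, sprintf("screen_%s.csv", g)),
    pruning = function(g) file.path(out_dir, sprintf("pruning_%s.csv", g)),
    report = file.path(out_dir, "report")
  )
}

#' Run the analysis pipeline
#'
#' Orchestrates `simulate` (synthetic cohort to session logs +
#' questionnaire CSV), `extract` (logs to per-game feature matrices),
#' `screen` (collinearity pruning + Spearman screen per game), and
#' `report` (CSV/text tables), exchanging every intermediate through
#' files so stages can be rerun in isolation. Returns a manifest of all
#' files written with their MD5 content hashes; reruns with the same
#' config and seed reproduce identical hashes for simulate/extract.
#'
#' @param config A [run_config()].
#' @param stages Subset of `c("simulate", "extract", "screen", "report")`.
#' @return Invisibly, a list with `manifest` (data frame: `file`, `md5`)
#'   and `counts` (named per-stage tallies).
#' @export
run_pipeline <- function(config, stages = c("simulate", "extract", "screen",
                                            "report")) {
  stopifnot(inherits(config, "run_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  p <- stage_paths(config$out_dir)
  written <- character()
  counts <- list()
  emit <- function(f) written <<- c(written, f)

  if ("simulate" %in% stages) {
    dir.create(p$data_dir, recursive = TRUE, showWarnings = FALSE)
    cohort <- generate_cohort(config$cohort)
    for (s in cohort$sessions) {
      f <- file.path(p$data_dir, sprintf("session_%s_%s.json",
                                         s$participant_id, s$game))
      write_session_log(s, f)
      emit(f)
    }
    write_questionnaire_table(cohort$questionnaires, p$questionnaires)
    emit(p$questionnaires)
    counts$sessions_written <- length(cohort$sessions)
    message(sprintf("simulate: %d sessions, %d questionnaire rows -> %s",
                    length(cohort$sessions), nrow(cohort$questionnaires),
                    config$out_dir))
  }

  if ("extract" %in% stages) {
    logs <- list.files(p$data_dir, pattern = "^session_.*\\.json$",
                       full.names = TRUE)
    if (!length(logs)) {
      stop("extract: no session logs under ", p$data_dir,
           " (run the simulate stage or point out_dir at existing logs)",
           call. = FALSE)
    }
    sessions <- lapply(sort(logs), read_session_log)
    games_here <- vapply(sessions, function(s) s$game, character(1))
    removed <- c(menu = 0L, sub_threshold = 0L)
    for (g in unique(games_here)) {
      feats <- extract_features(sessions[games_here == g], config$cleaning)
      write_feature_matrix(feats, p$features(g))
      emit(p$features(g))
    }
    for (s in sessions) {
      removed <- removed + attr(clean_swipes(s, config$cleaning), "removal_log")
    }
    counts$swipes_removed <- removed
    message(sprintf("extract: %d sessions -> %d feature matrices (removed %d menu, %d sub-threshold swipes)",
                    length(sessions), length(unique(games_here)),
                    removed[["menu"]], removed[["sub_threshold"]]))
  }

  if ("screen" %in% stages) {
    if (!file.exists(p$questionnaires)) {
      stop("screen: missing questionnaire table ", p$questionnaires, call. = FALSE)
    }
    scored <- score_questionnaire_table(read_questionnaire_table(p$questionnaires))
    write_questionnaire_table(scored, p$scored)
    emit(p$scored)
    n_tests <- 0L
    for (g in GAMES) {
      fpath <- p$features(g)
      if (!file.exists(fpath)) next
      feats <- utils::read.csv(fpath, stringsAsFactors = FALSE)
      res <- screen_features(feats, scored, config$screen)
      utils::write.csv(res, p$results(g), row.names = FALSE)
      utils::write.csv(attr(res, "pruning_log"), p$pruning(g), row.names = FALSE)
      emit(p$results(g)); emit(p$pruning(g))
      n_tests <- n_tests + nrow(attr(res, "all_tests"))
    }
    if (n_tests == 0L) {
      stop("screen: no feature matrices found under ", config$out_dir,
           " (expected features_<game>.csv from the extract stage)",
           call. = FALSE)
    }
    counts$tests_run <- n_tests
    message(sprintf("screen: %d Spearman tests run", n_tests))
  }

  if ("report" %in% stages) {
    any_written <- FALSE
    for (g in GAMES) {
      rpath <- p$results(g)
      if (!file.exists(rpath)) next
      res <- utils::read.csv(rpath, stringsAsFactors = FALSE)
      write_report(res, file.path(config$out_dir, sprintf("report_%s.csv", g)))
      emit(file.path(config$out_dir, sprintf("report_%s.csv", g)))
      emit(file.path(config$out_dir, sprintf("report_%s.csv.txt", g)))
      any_written <- TRUE
    }
    if (!any_written) {
      stop("report: no screen results found under ", config$out_dir, call. = FALSE)
    }
  }

  manifest <- data.frame(file = written,
                         md5 = unname(tools::md5sum(written)),
                         row.names = NULL, stringsAsFactors = FALSE)
  invisible(list(manifest = manifest, counts = counts))
}
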