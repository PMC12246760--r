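#' Instrument metadata
#'
#' Item counts and score ranges for the two screeners: GAD-7 (7 items,
#' totals 0--21) and PHQ-8 (8 items, totals 0--24). Items are rated 0
#' ("not at all") to 3 ("nearly every day") over the past two weeks.
#'
#' @param instrument `"GAD7"` or `"PHQ8"`.
#' @return A list with `n_items` and `max_total`.
#' @export
instrument_info <- function(instrument) {
  instrument <- match.arg(instrument, INSTRUMENTS)
  n_items <- if (instrument == "GAD7") 7L else 8L
  list(instrument = instrument, n_items = n_items, max_total = 3L * n_items)
}

#' Score a questionnaire response
#'
#' Totals are the plain arithmetic sum of the item ratings.
#'
#' @param items Integer vector of item ratings, each in 0--3; length 7 for
#'   GAD-7, 8 for PHQ-8.
#' @param instrument `"GAD7"` or `"PHQ8"`.
#' @return Integer total score.
#' @examples
#' score_questionnaire(rep(3, 7), "GAD7") # 21
#' @export
score_questionnaire <- function(items, instrument) {
  info <- instrument_info(instrument)
  if (length(items) != info$n_items) {
    stop(sprintf("%s requires %d item ratings, got %d",
                 info$instrument, info$n_items, length(items)), call. = FALSE)
  }
  if (anyNA(items) || !all(items %in% 0:3)) {
    stop(sprintf("%s item ratings must all be integers in 0..3", info$instrument),
         call. = FALSE)
  }
  as.integer(sum(items))
}

#' Default severity cutoffs
#'
#' Canonical bands for both instruments: 0--4 none, 5--9 mild, 10--14
#' moderate, >= 15 severe. For PHQ-8 this collapses "moderately severe"
#' and "severe" into a single top band so that both instruments report the
#' same four categories.
#'
#' @return Named numeric vector of lower cutoffs for mild/moderate/severe.
#' @export
default_cutoffs <- function() {
  c(mild = 5, moderate = 10, severe = 15)
}

#' Assign a severity band to a total score
#'
#' A nondecreasing step function of the total; every total maps to exactly
#' one of `none`, `mild`, `moderate`, `severe`.
#'
#' @param total Numeric vector of total scores.
#' @param instrument `"GAD7"` or `"PHQ8"`.
#' @param cutoffs Named vector of lower cutoffs, see [default_cutoffs()].
#' @return Character vector of bands.
#' @export
severity_band <- function(total, instrument, cutoffs = default_cutoffs()) {
  info <- instrument_info(instrument)
  if (anyNA(total) || any(total < 0 | total > info$max_total)) {
    stop(sprintf("total out of range [0, %d] for %s", info$max_total, info$instrument),
         call. = FALSE)
  }
  stopifnot(all(c("mild", "moderate", "severe") %in% names(cutoffs)),
            cutoffs[["mild"]] <= cutoffs[["moderate"]],
            cutoffs[["moderate"]] <= cutoffs[["severe"]])
  bands <- c("none", "mild", "moderate", "severe")
  idx <- 1L + (total >= cutoffs[["mild"]]) + (total >= cutoffs[["moderate"]]) +
    (total >= cutoffs[["severe"]])
  bands[idx]
}

#' Score a questionnaire table
#'
#' Adds `gad7_total`, `gad7_band`, `phq8_total`, `phq8_band` columns to a
#' questionnaire table in the layout produced by
#' [write_questionnaire_table()].
#'
#' @param tab Data frame with `gad7_q1..q7` and `phq8_q1..q8` columns.
#' @param cutoffs Severity cutoffs, see [default_cutoffs()].
#' @return The input data frame with four added columns.
#' @export
score_questionnaire_table <- function(tab, cutoffs = default_cutoffs()) {
  gcols <- paste0("gad7_q", 1:7)
  pcols <- paste0("phq8_q", 1:8)
  missing_cols <- setdiff(c("participant_id", gcols, pcols), names(tab))
  if (length(missing_cols)) {
    stop("questionnaire table lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  tab$gad7_total <- vapply(seq_len(nrow(tab)), function(i)
    score_questionnaire(as.integer(tab[i, gcols]), "GAD7"), integer(1))
  tab$phq8_total <- vapply(seq_len(nrow(tab)), function(i)
    score_questionnaire(as.integer(tab[i, pcols]), "PHQ8"), integer(1))
  tab$gad7_band <- severity_band(tab$gad7_total, "GAD7", cutoffs)
  tab$phq8_band <- severity_band(tab$phq8_total, "PHQ8", cutoffs)
  tab
}

#' Read / write the questionnaire CSV
#'
#' Layout: `participant_id, gad7_q1..gad7_q7, phq8_q1..phq8_q8, age_band,
#' sex, gamer_identity`.
#'
#' @param path File path.
#' @return `read_questionnaire_table()`: a data frame.
#' @export
read_questionnaire_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname read_questionnaire_table
#' @param tab Questionnaire data frame.
#' @export
write_questionnaire_table <- function(tab, path) {
  utils::write.csv(tab, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
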