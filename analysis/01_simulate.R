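#!/usr/bin/env Rscript
# Stage 1: simulate the study cohort.
#
# Synthesizes an 82-participant cohort under the default conditions: three
# 15-minute game sessions per participant (puzzle, infinite runner, object
# slicer), GAD-7/PHQ-8 item responses driven by correlated latent severity
# traits, the default planted-effect map, and 4 trailing participants with
# unlinkable device ids (so the linkage stage reproduces the 82 -> 78
# attrition). Raw session logs are bulky, so they go to scratch/; the
# questionnaire table and a cohort summary land in results/.

suppressPackageStartupMessages(library(swipesense))

seed <- 42
raw_dir <- "scratch/simdata"
dir.create(raw_dir, recursive = TRUE, showWarnings = FALSE)
dir.create("results", showWarnings = FALSE)

cfg <- cohort_config(n_participants = 82, seed = seed, unmatched_id_count = 4)
cohort <- generate_cohort(cfg)

for (s in cohort$sessions) {
  write_session_log(s, file.path(raw_dir, sprintf("session_%s_%s.json",
                                                  s$participant_id, s$game)))
}
write_questionnaire_table(cohort$questionnaires,
                          file.path(raw_dir, "questionnaires.csv"))

scored <- score_questionnaire_table(cohort$questionnaires)
write_questionnaire_table(scored, "results/questionnaires_scored.csv")

message(sprintf("Simulated %d sessions for %d participants (seed %d).",
                length(cohort$sessions), cfg$n_participants, seed))
message(sprintf("GAD-7 totals: mean %.2f (SD %.2f); PHQ-8: mean %.2f (SD %.2f)",
                mean(scored$gad7_total), sd(scored$gad7_total),
                mean(scored$phq8_total), sd(scored$phq8_total)))
message("Severity bands (GAD-7): ",
        paste(names(table(scored$gad7_band)), table(scored$gad7_band),
              collapse = ", "))
message("Raw logs in ", raw_dir, "; scored questionnaires in results/.")
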