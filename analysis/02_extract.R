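#!/usr/bin/env Rscript
# Stage 2: feature extraction.
#
# Reads the raw session logs written by 01_simulate.R, removes menu
# interactions and sub-threshold touches, recomputes per-swipe kinematics,
# Tukey-IQR filters each participant's per-swipe value sequences, and
# aggregates every session into its ~150-feature vector. One wide CSV per
# game goes to results/, along with the exported feature catalogs.

suppressPackageStartupMessages(library(swipesense))

raw_dir <- "scratch/simdata"
logs <- list.files(raw_dir, pattern = "^session_.*\\.json$", full.names = TRUE)
if (!length(logs)) stop("no session logs found; run analysis/01_simulate.R first")

sessions <- lapply(sort(logs), read_session_log)
games <- vapply(sessions, function(s) s$game, character(1))
cleaning <- cleaning_config()

removed <- c(menu = 0L, sub_threshold = 0L)
for (s in sessions) {
  removed <- removed + attr(clean_swipes(s, cleaning), "removal_log")
}
message(sprintf("Read %d sessions; cleaning removed %d menu swipes and %d sub-threshold touches.",
                length(sessions), removed[["menu"]], removed[["sub_threshold"]]))

for (g in unique(games)) {
  feats <- extract_features(sessions[games == g], cleaning)
  write_feature_matrix(feats, sprintf("results/features_%s.csv", g))
  write_catalog(build_catalog(g), sprintf("results/catalog_%s.csv", g))
  message(sprintf("%s: %d participants x %d features -> results/features_%s.csv",
                  g, nrow(feats), ncol(feats) - 2, g))
}
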