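#!/usr/bin/env Rscript
# Stage 3: correlation screen.
#
# Links feature rows to questionnaire records by participant id (dropping
# the unlinkable device ids), prunes collinear features at |r| >= 0.90,
# and screens every retained feature against GAD-7 and PHQ-8 totals with
# Spearman rank correlations (uncorrected p values, alpha = 0.05).
# Per-game results, pruning logs, and formatted report tables go to
# results/.

suppressPackageStartupMessages(library(swipesense))

scored <- read_questionnaire_table("results/questionnaires_scored.csv")
config <- screen_config()

for (g in c("puzzle", "runner", "slicer")) {
  fpath <- sprintf("results/features_%s.csv", g)
  if (!file.exists(fpath)) stop("missing ", fpath, "; run analysis/02_extract.R")
  feats <- utils::read.csv(fpath, stringsAsFactors = FALSE)
  linked <- feats$participant_id %in% scored$participant_id
  message(sprintf("%s: %d of %d feature rows link to questionnaires", g,
                  sum(linked), nrow(feats)))
  res <- screen_features(feats[linked, , drop = FALSE], scored, config)
  plog <- attr(res, "pruning_log")
  utils::write.csv(plog, sprintf("results/pruning_%s.csv", g), row.names = FALSE)
  write_report(res, sprintf("results/screen_%s.csv", g))
  message(sprintf("%s: %d features dropped as collinear; %d significant associations at alpha=%.2f",
                  g, nrow(plog), nrow(res), config$alpha))
  sig <- res[order(-abs(res$rho)), ]
  if (nrow(sig)) {
    top <- utils::head(sig, 5)
    message(paste(sprintf("  %s ~ %s: rho=%+.3f (p=%.3g)", top$feature_name,
                          top$instrument, top$rho, top$p_value),
                  collapse = "\n"))
  }
}
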