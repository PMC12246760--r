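# swipesense

Screening swipe-gesture telemetry from casual mobile games for behavioral
correlates of anxiety and depression.

## What this is

Swipe gestures made during ordinary mobile gameplay -- their speed,
contact-area pressure, screen position, and timing -- carry signatures of
psychomotor state, and psychomotor change is a core feature of both
depression and anxiety. `swipesense` implements, as an R package plus a
numbered analysis workflow, the full screening pipeline from raw
per-session swipe event logs and GAD-7/PHQ-8 questionnaire responses to a
table of feature-symptom Spearman correlations:

1. **Session I/O** -- read/validate JSON swipe event logs (full touch
   traces, pressures, device-motion streams), score questionnaires, and
   link gameplay records to questionnaire records by participant id.
2. **Feature extraction** -- drop menu interactions and sub-threshold
   touches, recompute per-swipe kinematics from the traces, remove
   outliers with Tukey's IQR rule, and aggregate each 15-minute session
   with 8 statistical functions (mean, median, max, min, SD, range,
   first, last) into a ~150-feature vector per participant and game.
3. **Correlation screen** -- prune collinear features (Pearson
   `|r| >= 0.90`, connected components, one representative per group),
   then test every retained feature against GAD-7 and PHQ-8 totals with
   Spearman rank correlation (rho over mid-ranks; exact permutation p for
   n <= 9, t approximation otherwise; uncorrected p values, alpha = 0.05).
4. **Synthetic cohorts** -- a seeded generator producing complete
   cohorts (latent severity traits, item responses, full per-game swipe
   and sensor streams) with *planted* effects whose strengths are
   calibrated so the end-to-end pipeline recovers stated Spearman
   targets. This stands in for raw participant telemetry, which is not
   publicly available for studies of this kind.

The methods vignette (`vignettes/swipe-screening-methods.Rmd`) documents
the statistical model, every tunable default, and the design choices made
where the underlying conventions were open.

## Worked example

The analysis workflow runs as numbered drivers from the repository root
(raw logs go to `scratch/`, tables to `results/`):

```sh
Rscript analysis/01_simulate.R        # 82-participant cohort, 3 games each
Rscript analysis/02_extract.R         # logs -> per-game feature matrices
Rscript analysis/03_screen.R          # pruning + Spearman screen
Rscript analysis/04_effect_recovery.R # 100-replicate recovery Monte-Carlo
```

Stage 1 prints the cohort's questionnaire summary:

```
Simulated 246 sessions for 82 participants (seed 42).
GAD-7 totals: mean 9.28 (SD 5.20); PHQ-8: mean 8.33 (SD 4.89)
Severity bands (GAD-7): mild 25, moderate 24, none 18, severe 15
```

i.e. the synthetic totals sit at the emulated sample moments (9.09 / 8.24)
up to one cohort's sampling noise. Stage 2 reads the 246 logs back,
removes 984 menu swipes and 2017 sub-threshold touches, and writes one
feature matrix per game (159 features for puzzle/runner, 155 for the
slicer). Stage 3 links 78 of the 82 feature rows (4 participants carry
corrupted device ids, reproducing the study's attrition), prunes 66-70
features per game as collinear, and prints the strongest screened
associations, e.g. for the puzzle game:

```
puzzle: 78 of 82 feature rows link to questionnaires
puzzle: 66 features dropped as collinear; 26 significant associations at alpha=0.05
  swipe_speed_last ~ PHQ8: rho=-0.403 (p=0.000253)
  swipe_speed_max ~ GAD7: rho=-0.370 (p=0.00086)
  swipe_duration_last ~ PHQ8: rho=+0.366 (p=0.000987)
```

Slower swiping (and its mirror image, longer durations) in participants
with higher severity -- the planted structure -- surfaces through
whichever collinear representative survives pruning; with ~190
uncorrected tests per game, a handful of the weaker hits in any single
cohort are the expected false positives of an exploratory screen. Stage 4
separates the two: across 100 replicate cohorts of n = 78, the mean
recovered correlation of each planted effect sits at its target:

```
  puzzle swipe_speed_mean               ~ PHQ8: target -0.405, recovered -0.379 (SD 0.102)
  puzzle swipe_speed_mean               ~ GAD7: target -0.400, recovered -0.406 (SD 0.090)
  puzzle swipe_end_press_variance_mean  ~ PHQ8: target -0.425, recovered -0.435 (SD 0.099)
  runner swipe_end_press_variance_mean  ~ PHQ8: target -0.405, recovered -0.402 (SD 0.103)
  slicer swipe_start_posY_min           ~ PHQ8: target +0.368, recovered +0.337 (SD 0.104)
  slicer swipe_press_min                ~ GAD7: target +0.430, recovered +0.434 (SD 0.089)
```

The same machinery is available programmatically:

```r
library(swipesense)
cohort <- generate_cohort(cohort_config(n_participants = 82, seed = 42))
scored <- score_questionnaire_table(cohort$questionnaires)
games  <- vapply(cohort$sessions, function(s) s$game, "")
feats  <- extract_features(cohort$sessions[games == "puzzle"])
screen_features(feats, scored)   # feature_name, instrument, rho, p_value, n
```

or through the stage orchestrator `run_pipeline(run_config(...))`, which
exchanges every intermediate through files and returns an MD5 manifest
(reruns with the same config and seed reproduce identical hashes).

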