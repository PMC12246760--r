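---
title: "Screening swipe-gesture telemetry for anxiety and depression correlates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening swipe-gesture telemetry for anxiety and depression correlates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swipesense)
```

## The problem

Casual mobile games are controlled almost entirely by swipe gestures, and
the kinematics of those gestures -- how fast a finger moves, how firmly it
presses, where on the screen it lands, how long it pauses between moves --
carry information about the player's psychomotor state. Psychomotor
slowing and agitation are core features of depression and anxiety, so
per-swipe telemetry collected during ordinary gameplay is a candidate
digital biomarker for both.

`swipesense` implements the full screening pipeline for this setting:

1. read per-session swipe event logs (JSON) and GAD-7/PHQ-8 questionnaire
   tables, and link them by participant id;
2. clean the raw streams, recompute per-swipe kinematics from the touch
   traces, remove outliers, and aggregate each 15-minute session into a
   per-participant feature vector (~150 features per game);
3. prune collinear features and screen the remainder against anxiety and
   depression totals with Spearman rank correlations.

Because raw participant telemetry of this kind is never publicly
deposited, the package also ships a synthetic cohort generator that
emulates the study design -- three game archetypes, 15-minute sessions,
item-level questionnaire responses -- with *planted* effects of known
strength, so that every stage of the pipeline is testable end to end and
its statistical calibration can be demonstrated rather than assumed.

## Data model

A `game_session` is one participant x game play record. Swipes carry the
full per-swipe metric set logged by the games (identifiers, launch- and
level-anchored timestamps, start/end positions, the complete touch trace,
contact-area pressures and their local variances, speed, duration,
distance, quantized direction, inter-swipe gap). Device motion is recorded
independently of swipes as free-running accelerometer and gyroscope
streams.

Conventions chosen where the logging format left them open:

* **Coordinates**: origin at the bottom-left of the screen in the
  session's orientation, y increasing upward, units pixels. Default
  screen is 1080x2400 (portrait, runner) or 2400x1080 (landscape, puzzle
  and slicer). With this convention "higher on the screen" means larger
  `posY`, which makes the sign of position-derived correlations directly
  interpretable.
* **Pressure** is a dimensionless fingertip contact-area proxy normalized
  to [0, 1]; capacitive screens do not measure true force.
* **Times**: `event_time` is anchored at game launch; `start_time` /
  `end_time` at level load. All seconds, stored as doubles.
* **Duplicate swipe ids** within a session are an error; ids need not be
  globally unique.
* The slicer game has no quantized swipe direction (its gameplay is
  free-form slicing), so its swipes carry direction `"none"`; puzzle and
  runner swipes are quantized to up/down/left/right by the dominant axis,
  with ties broken toward horizontal.

The JSON dialect (one object per swipe, exact logged field names,
touch trace as `[t, x, y, press]` quadruples, columnar sensor arrays) is
documented by the schema file shipped at
`system.file("extdata", "session_log.schema.json", package = "swipesense")`.
No R JSON-Schema validator is assumed: `read_session_log()` enforces the
same constraints in code and reports every violation with its field name.

## Questionnaire scoring

GAD-7 (7 items) and PHQ-8 (8 items) are scored as plain sums of 0-3 item
ratings, giving totals in 0-21 and 0-24. Severity bands use the
instruments' canonical cutoffs -- 0-4 none, 5-9 mild, 10-14 moderate,
15+ severe -- with PHQ-8's "moderately severe" and "severe" collapsed
into one top band so both instruments report four categories. The cutoffs
are an argument (`severity_band(total, instrument, cutoffs = ...)`)
because band boundaries are a reporting convention, not part of the
statistics.

## Feature extraction

**Cleaning.** Swipes logged outside the session's gameplay window are
menu interactions and are dropped. Touches whose path length falls below
`min_swipe_distance` are taps or palm grazes, not intentional swipes;
the default threshold is 20 px (about 2 mm at ~10 px/mm -- well below any
plausible intentional swipe, well above tap jitter). Both removals are
tallied in a per-reason log.

**Per-swipe kinematics** are recomputed from the touch trace rather than
trusted from the log: distance is the sum of consecutive segment lengths
("total screen covered"), duration the trace's time span, and speed is
distance/duration over that same total-path distance. A
displacement-based speed mode exists for sensitivity analysis
(`cleaning_config(speed_mode = "displacement")`). Start- and end-pressure
variances are computed over the first/last *k* = 5 trace points (all
points when fewer); the window size is a package choice, as event logs do
not define "the pressure while the swipe was starting" more precisely.

**Outliers.** Each per-swipe value sequence is Tukey-filtered: values
outside `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]` are removed, with quartiles by the
linear-interpolation rule and sequences shorter than 4 passed through.
The 1.5 multiplier is Tukey's convention. Whether outlier removal should
act on per-swipe values within a participant or on aggregated features
across participants is genuinely ambiguous in this design; the default is
`per_participant_metric` (filter each participant's own swipe sequence
before aggregation, which is the reading consistent with "remove outliers
from the dataset" of trace data), and a `pooled_metric` mode masks
cross-participant feature outliers instead.

**Aggregation.** Each base metric is summarized across the session with
the eight statistical functions (mean, median, maximum, minimum, SD,
range, first, last), applied "wherever appropriate":

* position and kinematic scalars (start/end positions, speed, duration,
  distance, inter-swipe gap): all eight;
* pressure scalars: all but `first` (the opening swipe of a session
  reflects initial grip adjustment rather than steady-state play);
* pooled touch-trace coordinates and sensor axes: the six order-free
  aggregators only -- `first`/`last` are meaningless for free-running
  sequences not aligned to swipe onsets;
* plus the retained swipe count, and per-direction counts for the two
  directional games.

Sample (n-1) SD is used throughout. This composition yields 159 features
for puzzle/runner and 155 for the slicer -- the "approximately 150"
regime. The exact composition is a package choice: the full metric
enumeration behind the original figure is not public, so `build_catalog()`
is the package's own deterministic definition of the feature space, and
every downstream result names features from it.

## The correlation screen

**Collinearity pruning.** With ~150 features per game, many are
near-duplicates (speed and distance; a mean and its median). Features
linked by pairwise-complete Pearson `|r| >= 0.90` are grouped into
connected components, and each group is reduced to one representative.
Connected components (rather than greedy pairwise merging) make the
grouping order-independent. The representative is chosen by a configurable
priority order -- speed bases first, then SD-type pressure summaries, then
pressure variances, positions, and distance/duration last -- encoding the
preference for clinically interpretable kinematic features (speed over
distance, variability over level), with a lexicographic tie-break for
determinism. Absolute r is used because a feature that is perfectly
anti-correlated with another is just as redundant.

**Spearman screen.** Every retained feature is tested against both
questionnaire totals. rho is the Pearson correlation of mid-ranks
(average ranks for ties); the two-sided p value uses exact permutation
enumeration for n <= 9 and the t approximation with n - 2 df otherwise.
Constant features yield an undefined result and are excluded rather than
reported. No multiple-comparison correction is applied by default: the
screen is explicitly exploratory, meant to nominate features for
confirmatory follow-up, and corrected screening is available but off
(`screen_config(correction = "BH")`).

## The synthetic cohort generator

The generator's defaults *are* the study conditions: n = 82 participants
(with 4 optionally carrying unlinkable device ids, reproducing the
82 -> 78 attrition), three 15-minute sessions each, and questionnaire
totals whose population mean/SD match the emulated sample (9.09/5.26 for
GAD-7, 8.24/4.95 for PHQ-8).

**Latent structure.** Each participant has standard-normal anxiety and
depression traits with correlation 0.6. The source cohort reports both
instruments but not their inter-score correlation; 0.6 is in the typical
range for GAD-7/PHQ co-administration and is a flagged, configurable
default (`cohort_config(latent_cor = ...)`).

**Item responses** discretize the trait: rating =
`clamp(round(a0 + a1 * trait + e), 0, 3)` with item noise `e ~ N(0, 0.8)`.
The constants (GAD-7: a0 = 1.2518, a1 = 0.8633; PHQ-8: a0 = 0.9409,
a1 = 0.6946) were calibrated once by large-n simulation against the target
total moments and then frozen.

**Sessions.** Swipe counts are Poisson (means 350/500/400 for
puzzle/runner/slicer -- large enough that per-participant aggregates are
stable over a 15-minute session). Per-swipe speeds are lognormal around a
participant-level mean speed; path lengths are lognormal per game (slicer
swipes are longer, matching its continuous slicing interaction); paths are
line/arc segments with per-point jitter, quantized directions for
puzzle/runner, arbitrary angles for the slicer; per-point pressures sit at
a participant's level with segment-specific jitter amplitudes (a separate
end-of-swipe amplitude is what the end-pressure-variance features
measure). Device motion is white noise at 50 Hz with participant-level
amplitude. Menu swipes before/after the gameplay window and occasional
sub-threshold taps are included so the cleaning stage always has work to
do. None of the per-swipe scales is reported in the source -- the
telemetry distributions are invented, labelled defaults -- so what the
generator supports is *relative* and *structural* claims (calibration,
recovery, invariances), not raw-signal realism. Real touch traces also
exhibit autocorrelation, drift, fatigue and learning effects over a
session, none of which are modelled; passing tests therefore demonstrate
that the pipeline measures what it claims to measure, not that the
generator reproduces real gameplay.

**Planted effects.** Each default effect entry couples one mechanism
parameter to the traits. The coupling is specified as `latent_rho`, the
correlation between the participant's parameter (on its latent scale) and
the targeted trait; trait loadings are solved from the bivariate trait
covariance (so one parameter can carry stated couplings to both
instruments, as puzzle swipe speed does), and the remaining variance is
independent participant noise. Mechanisms are monotone maps to positive
scales: log-linear for speed and end-pressure amplitude, probit
(`pnorm`) for the two slicer floors (minimum start height in
[120, 380] px; pressure floor in [0.12, 0.27]), which keeps every
parameter in its physical range. Floor-type mechanisms were chosen for the
`min`-aggregator targets because the minimum of ~400 draws estimates a
distributional floor with very little noise, making the planted ordering
survive aggregation.

A planted `latent_rho` is *not* the recovered correlation: item noise and
clamping attenuate trait-total correlations to ~0.93 (GAD-7) / ~0.90
(PHQ-8), and aggregation adds a little more. `calibrate_effect()`
inverts this attenuation by Monte-Carlo search; the shipped defaults were
calibrated with it (measure mean recovered rho over many replicate
cohorts at n = 78, apply a proportional correction, verify on an
independent seed) and then frozen. Recovery runs skip sensor synthesis:
session seeds draw all swipe randomness first, so swipe-derived features
are bit-identical with or without the streams (a property the test suite
asserts).

**Reproducibility.** Every draw derives from the master seed through
per-component sub-seeds (traits, questionnaires, demographics, each
session), so a cohort is byte-reproducible, and restricting the games to
synthesize leaves the questionnaire table and the remaining sessions
unchanged.

## Numerical and degenerate-input choices

* IQR filtering: type-7 (linear interpolation) quantiles; n < 4 passes
  through; ties produce IQR = 0 and fences at the common value.
* Sample SD everywhere; a single value has SD 0 by convention in
  aggregation (`std` of one retained swipe).
* `spearman_cor` drops incomplete pairs first, requires >= 3, and treats
  constant inputs as undefined results, not errors.
* Exact Spearman p values enumerate all n! permutations (cached per n up
  to 9) and count `|rho| >= |observed| - 1e-12` to absorb float noise.
* Zero-displacement direction quantization is an error by contract:
  such touches are taps and must be filtered before derivation.
* Sessions with no retained swipes aggregate to `swipe_count = 0` with
  all swipe features missing; constant features are flagged `NA` in the
  Pearson matrix and skipped by the screen.

## Problem sizes used in validation

The packaged validation runs use: 100 replicate cohorts of n = 82
(questionnaire calibration) and 100 replicate cohorts of n = 78 through
the full extract-and-screen pipeline (planted-effect recovery, tolerance
±0.05 on each mean recovered rho); the null-calibration checks pool
~1000 screen-level replicates at n = 78 and 40 full-pipeline replicates
with scaled-down sessions, asserting a false-positive rate in
[0.03, 0.07] at alpha = 0.05. These sizes give Monte-Carlo standard
errors comfortably below the tolerances they are checked against.

## Known limitations

* The generator's telemetry scales are invented; only rank-based,
  calibrated quantities transfer to real data.
* The feature catalog is this package's enumeration of the ~150-feature
  space, not a reconstruction of any specific deployment's list.
* Pruning keeps one representative per collinear group; if two collinear
  features have genuinely different clinical meanings, the priority list
  is the only thing distinguishing them.
* Uncorrected p values at alpha = 0.05 over ~300 tests per game imply
  ~15 false positives per game under the null -- by design, as a
  nomination screen. Use `correction = "BH"` for anything confirmatory.
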