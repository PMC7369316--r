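---
title: "Methods: format-dependent encoding of observed manipulative actions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: format-dependent encoding of observed manipulative actions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

Neurons in parietal cortex respond to videos of observed manipulative
actions (OMAs) — drag, drop, grasp, push, roll, rotate, squeeze — and those
responses change with the purely visual *format* of the video: the actor's
posture (standing/sitting) crossed with the camera viewpoint
(lateral/frontal). The central question this package operationalizes is
*how* single units mix action identity with format: if the format acts as a
multiplicative gain on a fixed action-tuning profile, each unit's exemplar
*ranking* is preserved across formats and a stable population read-out of
action identity is possible despite large changes in retinal input; if
instead format and action mix additively, or units carry format-specific
("mixed") selectivity, the ranking need not survive a format change.

`omapop` implements the complete analysis chain on trial-aligned spike
data: epoching and binning, ANOVA-based unit classification, additive vs.
multiplicative response-matrix models with split-half cross-validation,
Poisson naive Bayes (PNB) pseudopopulation decoding with temporal
generalization and permutation nulls, the across-format rank stability
index (RSI), and Mahalanobis-linkage clustering of condition means. Since
no public recordings accompany the design, a ground-truth-labelled
synthetic generator reproduces the statistical structure every stage
assumes, making the whole chain testable end to end.

## The synthetic generator

A main session is the full factorial design: 7 exemplars x 4 formats x
2 actors x 2 objects x 3 repetitions = 336 trials (12 per exemplar x
format cell, 112 distinct videos), with a 500-ms pre-onset baseline and
2.6-s videos; presentation order is randomized. Spiking is an
inhomogeneous Poisson process with a piecewise-linear rate:

* baseline rate before onset;
* a *static*, format-dependent step at video onset (the actor's initial
  posture is visible immediately);
* a *dynamic*, exemplar-dependent component ramping linearly from 300 ms
  to the end of epoch 2 (1.5 s) and sustained to video end.

The ramp endpoint is chosen so the epoch-2 time-average equals the unit's
expected rate matrix exactly, by class:

| class | epoch-2 expectation (format j, exemplar i) |
|---|---|
| `multiplicative_stable` | baseline + gain_j x tuning_i |
| `additive` | baseline + gain_j + tuning_i |
| `mixed_unstable` | baseline + per-format tuning\[j, i\] (rows independent) |
| `format_only` | baseline + gain_j |
| `untuned` | baseline |

Sampling is exact rather than grid-based: each linear segment's spike
count is Poisson with mean equal to the integral of the rate, and spike
times follow the segment's inverse CDF. Actor and object add a zero-mean
rate jitter (default SD 5% of the tuning amplitude — the design treats
them as nuisance visual variability; no quantitative value is available,
so this is a package choice). The jitter is shrunk per unit whenever it
could push a low-rate segment negative, because clamping at zero would
bias condition means. One master seed expands into per-unit substreams via
a fixed integer hash, so any subset of units regenerates identically.

Default population parameters (chosen once as realistic for visual
parietal neurons): baselines uniform on 5-15 spikes/s; multiplicative
tuning gamma-distributed (~10 sp/s mean drive) with log-normal format
gains (SD 0.35 on the log scale, clipped to [0.4, 2.5]); additive gains
and tuning uniform on a common 0-20 sp/s scale. The common scale for the
additive class matters: classes should differ in their *mixing rule*, not
in drive strength, otherwise model comparisons confound the two.

The control session emulates 9 natural videos (3.5 s, 10 trials each)
with fixed normalized motion and contrast covariates. `motion_coupled`
units fire at baseline + slope x motion during the video; other classes
receive a constant per-video effect recycled from their main-experiment
tuning (the control analyses are epoch-level, so no within-video dynamics
are modelled). What the generator does *not* emulate: non-Poisson
variability (bursting, refractoriness), rate correlations between
simultaneously recorded units, slow drift across a session, and
eye-movement artefacts. Passing tests therefore validate the analysis
chain under its stated assumptions, not the biology of any particular
area.

## Unit classification

The "repeated-measures" ANOVAs are realized as split-plot designs with
trials as subjects: per format, a 3 x 7 ANOVA with epoch
(baseline/epoch 1/epoch 2) within trials and exemplar between trials,
fitted by `aov()` with an `Error(trial)` stratum. A unit is
*action-related* if the epoch factor (main or interaction) is significant
in at least one format and a Bonferroni-corrected paired post hoc confirms
epoch 1 and/or epoch 2 differs from baseline; *OMA-selective* if the
exemplar factor (main or interaction) is additionally significant.
Because the selectivity gate pools 8 tests (2 effects x 4 formats) at
alpha = 0.05, about a third of truly untuned-but-responsive units are
promoted to OMA-selective by chance; this familywise behaviour is
intrinsic to the described procedure and is asserted as such in the tests.

The control classification is the analogous 2 x 9 design (epoch x video)
with a Fisher LSD gate (unadjusted paired comparison conditional on a
significant omnibus). The motion/contrast screen correlates each unit's
nine per-video mean rates with the motion and contrast covariates
(Pearson, n = 9) and flags significant motion correlations for exclusion.
The tuned-fraction time course runs per-unit one-way ANOVAs in 150-ms
bins (50-ms steps); each bin's tuned fraction is compared with the mean
pre-onset fraction by a 2 x 2 chi-squared test (no continuity correction;
bins must exceed baseline to be flagged). A preference index
PI = (n − sum_i lambda_i / lambda_max) / (n − 1) over the exemplar means
is provided for descriptive use; its exact form is a package choice.

## Mixing models

Per unit, the 4 x 7 epoch-2 response matrix from one half of the trials
(even-numbered, or random halves) is the held-out matrix `O`; the other
half gives the training matrix `O'`. The *additive* prediction is
`A_ij = k1 E_i + k2 F_j`, with `E` the exemplar (column) means and `F` the
format (row) means of `O'`. The constants are estimated by OLS *with a
nuisance intercept*: `E` and `F` each contain the shared baseline, and a
regression through the origin forces `k1 + k2 ~ 1` while distorting the
relative weights whenever the exemplar- and format-marginal variances
differ — noise-free additive data would then cap at R² ~ 0.94 while the
rank-1 model reaches ~0.99 by absorbing the constant, inverting the
intended comparison. With the intercept (which the translation-invariant
correlation statistic never sees), additive data recover R² = 1 and the
double dissociation is clean in both directions. The *multiplicative*
prediction is the leading rank-1 SVD reconstruction `M = s1 u1 v1'` of
`O'` — by Eckart-Young the best rank-1 approximation in Frobenius norm.
Model accuracy is the squared Pearson correlation between prediction and
`O` over the 28 entries; `O'` vs `O` gives the split-half reliability
(noise ceiling). Population comparison uses medians and two-sided
Mann-Whitney U tests (tie-corrected normal approximation; exact p when a
group has under 8 values). One asymmetry is worth knowing: on purely
additive populations the additive model's median advantage is real but
small (~0.01-0.02), because the rank-1 model absorbs the baseline
constant and approximates additive structure well; the recovered
dissociation property on that side is therefore the median ordering,
whereas on multiplicative populations the multiplicative advantage is
large and significant. The constants are fitted on the training half
by default (`constants_on = "test"` reproduces the alternative reading of
the procedure). The time-resolved variant repeats the fit in 150-ms
windows (50-ms steps) over 20 random splits per window, averages per
unit, and tests pairwise differences with a sliding Wilcoxon signed-rank
test, reporting only runs of at least 4 consecutive significant windows.

## Decoding

Units recorded separately are assembled into pseudopopulations: per unit,
trials of each condition are randomly distributed across splits, one data
point per condition per split. The split structure follows the factorial
arithmetic of the design — conditions are the 7 exemplars, with the
decoded format factor riding along as a class label where applicable:
48 x 7 = 336 data points for format-independent OMA decoding, 24 x 7 =
168 for viewpoint or posture decoding, 12 x 7 = 84 for single-format OMA
(cross-)decoding. The classifier is Poisson naive Bayes on raw spike
counts in 150-ms bins: lambda is the per-unit, per-class mean training
count floored at 1/(2 x training points); the predicted class maximizes
`sum_u (n_u log lambda_uc − lambda_uc)`; ties break to the lowest class
index. Raw counts are used because Poisson likelihoods require
nonnegative integers; a z-scored template-correlation classifier (z-score
parameters from training splits only) is available as
`method = "correlation"` for rate-normalized decoding. Accuracy is
leave-one-split-out cross-validated, averaged over resample runs (50 at
full scale), and computed for every train-bin x test-bin pair (temporal
generalization; bin labels refer to bin starts). Significance uses a
permutation null — per unit, condition labels shuffled before
pseudopopulation assembly — with a bin significant only when real
accuracy exceeds *all* null values, retained in runs of at least 4
consecutive bins; the onset is the start of the first significant bin.

## Rank stability index

In 500-ms bins stepped by 20 ms, exemplars are ranked per format by
trial-averaged rate (rank ties break by fixed exemplar order). With
reference format `stand_lateral` (any format can serve; a robustness
helper repeats the analysis under each), `Rf_i` is the rank, in each of
the 3 test formats, of the reference format's preferred exemplar, and

    RSIr = 1 + sum_{i=1..3} (1 − (1/7)(Rf_i − 1)),

ranging from 10/7 (worst everywhere) to 4 (best everywhere). The
normalization `(RSIr − 10/7) / (4 − 10/7)` maps the achievable range onto
[0, 1]; the denominator is the range, not the maximum, because only that
choice spans [0, 1]. Full enumeration of the 343 equally likely rank
triples gives 19 equally spaced achievable values and an exact null mean
of 0.5. Two nulls are provided: unconstrained (every `Rf_i` in every bin
replaced by an independent uniform draw on 1..7) and constrained (per
test format, one random value map applied to all bins, preserving the
temporal structure of selectivity changes; drawn with replacement per the
procedure's wording, with a bijective variant behind a flag). The total
score sums normalized RSI over bins lying entirely within epochs 1+2;
sorting units by total score and labelling the top floor(n/2) as stable
reproduces the 56/57 split convention at n = 113. Being rank-based, the
index is invariant to any monotone rescaling of rates within a format.

## State-space clustering

Trial-averaged rates in 60-ms/20-ms bins over epochs 1+2 form a units x
(conditions x time points) matrix; each condition's time points are its
cloud in the N-dimensional state space. Distances between condition
centroids are Mahalanobis under the pooled within-condition covariance,
divided by N (the distance grows linearly with population size). Because
N typically exceeds the number of samples, the covariance is
ridge-regularized as `W + gamma trace(W)/N I` with gamma = 0.1 — the
limiting behaviour is transparent (large gamma recovers scaled Euclidean
distances) and results are insensitive to gamma within an order of
magnitude. Distances are computed in the raw unit space (not a
discriminant projection); this is the documented choice where the
procedure's source is ambiguous. Trees use average linkage (UPGMA) with
an exact optimal-leaf-ordering dynamic program (leaf order minimizes the
sum of adjacent-leaf distances among orders consistent with the tree);
tie-breaks follow label order. The epoch and bin size of the clustering
are package defaults (the source procedure does not state them).

## Numerical and scale choices

* Time is in seconds, double precision, onset = 0; bins are half-open
  `[start, start + width)` so edge spikes have a deterministic home.
* Epoch 2 is fixed at `[0.3, 1.5)` s for every exemplar (its duration
  balances the differing OMA durations); no per-exemplar adjustment.
* The test suite and analysis scripts run the full procedures at reduced
  problem sizes chosen for a laptop-class budget: populations of 30-100
  units, 5-10 resample runs and 10-20 shuffles where the full-scale
  procedure uses 50/50, and 50-seed property suites. These sizes are
  stated in each script; the procedures themselves are identical at any
  scale.
* Degenerate inputs are handled explicitly: zero-variance units are
  classified without an ANOVA, constant held-out matrices yield undefined
  correlations (dropped from population statistics, logged), all-zero
  training matrices give a zero multiplicative model, and tied leading
  singular values or tied ranks are logged with deterministic tie-breaks.

## Known limitations

* The generator's Poisson assumption matches the PNB classifier's model;
  real spike trains are over- or under-dispersed, so absolute decoding
  accuracies here are optimistic relative to real data.
* The split-plot ANOVA treats epoch rates within a trial as uncorrelated
  repeated measures with possibly unequal variances (epoch durations
  differ); no sphericity correction is applied, matching the procedure's
  description. Calibration at the null is verified empirically in the
  acceptance suite.
* Printed headline numbers of the motivating study (unit counts, decoding
  latencies, medians, t statistics) depend on the unavailable recordings
  and are out of scope; the package validates the machinery through exact
  combinatorial identities and generative-recovery properties instead.
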