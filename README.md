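# omapop

Population analysis of how single neurons encode **observed manipulative
actions (OMAs)** across changes in visual presentation **format**.

## The problem

When a monkey watches videos of hand actions — drag, drop, grasp, push,
roll, rotate, squeeze — parietal neurons respond selectively to action
identity, but their firing also depends on purely visual format: the
actor's posture (standing/sitting) crossed with the camera viewpoint
(lateral/frontal). The scientific question is *how* a unit mixes the two
factors. If format acts as a **multiplicative gain** on a fixed
action-tuning profile,

    r_ij = baseline + g_j * t_i        (format j, exemplar i)

then the exemplar *ranking* is identical in every format and a
population read-out of action identity survives format changes. If the
factors mix **additively** (`r_ij = baseline + g_j + t_i`) or with
format-specific mixed selectivity, rank stability is not implied.

`omapop` implements the full analysis chain for this question, plus a
ground-truth-labelled synthetic spike generator (7 exemplars x 4 formats
x 2 actors x 2 objects x 3 repetitions = 336 trials/session) so every
stage is testable without external recordings:

* **recording model & binning** — trial-aligned spike tables, half-open
  sliding bins, epoch rates (baseline `[-0.5, 0)`, epoch 1 `[0, 0.3)`,
  epoch 2 `[0.3, 1.5)` s), baseline-subtracted population activity;
* **unit classification** — split-plot epoch x exemplar ANOVAs per
  format, the 2 x 9 control-experiment screen, motion/contrast exclusion,
  tuned-fraction time courses;
* **mixing models** — additive (`A_ij = k1 E_i + k2 F_j`) vs.
  multiplicative (leading rank-1 SVD, `M = s1 u1 v1'`) predictions with
  split-half cross-validation, Mann-Whitney population comparison, and a
  time-resolved variant with sliding Wilcoxon masks;
* **decoding** — Poisson naive Bayes pseudopopulation decoding
  (48x7 = 336 / 24x7 = 168 / 12x7 = 84 data-point configurations),
  temporal generalization matrices, permutation nulls with >= 4
  consecutive-bin masks, cross-format generalization;
* **rank stability index** — `RSIr = 1 + sum_i (1 - (Rf_i - 1)/7)` over
  the 3 test formats in sliding 500-ms bins, normalized to [0, 1]
  (19 achievable values, exact null mean 0.5), shuffled and
  constrained-shuffled nulls, stable/unstable population split;
* **state-space clustering** — Mahalanobis distances between condition
  means (pooled ridge-regularized covariance, normalized by N) with
  UPGMA dendrograms and optimal leaf ordering.

## Worked example

```r
library(omapop)

## a small population with known ground truth
pop <- sample_population(
  40, class_mix = c(multiplicative_stable = 0.5, mixed_unstable = 0.5),
  seed = 1)
rec <- generate_main_dataset(pop, design_spec(), seed = 1)
rec
#> <recording_set [main]: 40 units, 336 trials, 871916 spikes>

## additive vs multiplicative mixing in epoch 2
cmp <- compare_models_population(fit_mixing_population(rec))
round(cmp$medians, 3)
#>       r2_observed r2_multiplicative       r2_additive
#>             0.890             0.658             0.649

## across-format rank stability and the stable/unstable split
tcs <- rsi_population(rec, width = 0.5, step = 0.1)
sp  <- stability_split(vapply(tcs, `[[`, 0, "total_score"))
table(sp$stability_label)
#>   stable unstable
#>       20       20

## format-independent OMA decoding (epoch-2 window, 7-way, chance 1/7)
bt <- bin_rates(rec, 1.2, 1.2, c(0.3, 1.5))
decode_factor(bt, "exemplar", n_runs = 5, seed = 2)$diagonal
#> [1] 0.9922619
```

The split-half reliability (0.89) is the noise ceiling; for this
half-multiplicative population the rank-1 (gain) model edges out the
additive model at the median (on a pure multiplicative population the gap
is large). The stability split separates the two generative classes by
total RSI score, and the pseudopopulation decodes the seven actions far
above the 0.143 chance level.

The `analysis/` directory holds the same pipeline as a numbered workflow
(`01_simulate.R` ... `06_state_space.R`) writing tables under `results/`;
each script prints a one-line summary of what it found.

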