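#!/usr/bin/env Rscript
## Additive vs. multiplicative mixing of format and OMA identity:
## epoch-2 split-half fits per unit, population medians with Mann-Whitney
## comparisons, and the time-resolved model comparison with sliding
## Wilcoxon masks.

library(omapop)

rec <- read_recording_set("results/data/main")
cl <- data.table::fread("results/classification_main.csv",
                        colClasses = list(character = "unit_id"))
sel <- cl[main_label == "oma_selective", unit_id]
cat("fitting mixing models for", length(sel), "OMA-selective units\n")

rec_sel <- rec
rec_sel$units <- rec$units[unit_id %in% sel]
rec_sel$spikes <- rec$spikes[unit_id %in% sel]

fits <- fit_mixing_population(rec_sel)
data.table::fwrite(fits, "results/mixing_fits_epoch2.csv")
cmp <- compare_models_population(fits)
print(round(cmp$medians, 3))
print(cmp$tests)
data.table::fwrite(cmp$tests, "results/mixing_population_tests.csv")

tres <- time_resolved_comparison(rec_sel, n_repeats = 20, seed = 77,
                                 window = c(0, 2.55))
data.table::fwrite(tres$mean_r2, "results/mixing_timecourse.csv")
masks <- data.table::as.data.table(tres$masks)
masks[, bin_start := tres$bin_starts]
data.table::fwrite(masks, "results/mixing_timecourse_masks.csv")
cat("windows where multiplicative > additive is sustained:",
    sum(tres$masks$multiplicative_vs_additive), "of",
    length(tres$bin_starts), "\n")
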