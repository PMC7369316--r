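#!/usr/bin/env Rscript
## Simulate the synthetic recording sessions used by the downstream
## analysis scripts: a main session (7 OMA exemplars x 4 formats, 336
## trials) for a mixed 60-unit population, and a control session (9
## natural videos, 10 trials each) for the same population plus
## motion-coupled units. Writes plain-text recording sets under
## results/data/.

library(omapop)

seed <- 20260927L
dir.create("results/data", showWarnings = FALSE, recursive = TRUE)

pop <- sample_population(
  60,
  class_mix = c(multiplicative_stable = 0.3, additive = 0.2,
                mixed_unstable = 0.2, format_only = 0.1, untuned = 0.2),
  seed = seed)
rec <- generate_main_dataset(pop, design_spec(), seed = seed)
write_recording_set(rec, "results/data/main")
cat(sprintf("main session: %d units, %d trials, %d spikes\n",
            nrow(rec$units), nrow(rec$trials), nrow(rec$spikes)))

## control population: the same archetypes plus motion-coupled units that
## the exclusion screen should catch
pop_ctl <- c(pop[1:50],
             lapply(51:60, function(i)
               unit_spec(i, "motion_coupled", baseline_rate = 10,
                         motion_slope = 25)))
ctl <- generate_control_dataset(pop_ctl, design_spec(), seed = seed + 1L)
write_recording_set(ctl$recordings, "results/data/control")
data.table::fwrite(ctl$covariates, "results/data/control_covariates.csv")
cat(sprintf("control session: %d units, %d trials (9 videos x 10)\n",
            nrow(ctl$recordings$units), nrow(ctl$recordings$trials)))
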