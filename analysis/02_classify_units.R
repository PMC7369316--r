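#!/usr/bin/env Rscript
## Unit classification: per-format 3 x 7 (epoch x exemplar) split-plot
## ANOVAs on the main session; 2 x 9 ANOVAs and the motion/contrast
## exclusion screen on the control session; time-resolved tuned-fraction
## curves for exemplar, viewpoint and posture.

library(omapop)

rec <- read_recording_set("results/data/main")
ctl <- read_recording_set("results/data/control")
covs <- data.table::fread("results/data/control_covariates.csv")

cl_main <- classify_main(rec)
data.table::fwrite(cl_main, "results/classification_main.csv")
print(table(cl_main$main_label))
gt <- rec$ground_truth[match(cl_main$unit_id, unit_id)]
cat("selective among multiplicative/mixed/additive units:",
    mean(cl_main[gt$unit_class %in% c("multiplicative_stable", "additive",
                                      "mixed_unstable"),
                 main_label] == "oma_selective"), "\n")

cl_ctl <- classify_control(ctl)
data.table::fwrite(cl_ctl, "results/classification_control.csv")
print(table(cl_ctl$control_label))

vm <- video_epoch_means(ctl)
scr <- motion_contrast_screen(vm, covs)
data.table::fwrite(scr, "results/motion_screen.csv")
cat("units excluded for motion coupling:", sum(scr$excluded_for_motion), "\n")

sel <- cl_ctl[control_label == "video_selective", unit_id]
if (length(sel) >= 2) {
  pref <- population_video_preference(vm[rownames(vm) %in% sel, , drop = FALSE])
  data.table::fwrite(pref$pairwise, "results/video_preference_pairwise.csv")
  cat("video-preference omnibus P:", signif(pref$omnibus_p, 3), "\n")
}

for (f in c("exemplar", "viewpoint", "posture")) {
  tf <- tuned_fraction_timecourse(rec, f)
  data.table::fwrite(tf, sprintf("results/tuned_fraction_%s.csv", f))
  on <- tf$bin_start[which(tf$significant)[1]]
  cat(sprintf("%s tuning: peak fraction %.2f, first significant bin %s s\n",
              f, max(tf$fraction), ifelse(is.na(on), "none", on)))
}
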