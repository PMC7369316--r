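test_that("constant-rate units are task-unrelated, responsive units are found", {
  rec <- generate_main_dataset(list(flat_unit("flat"),
                                    step_unit("step", step = 12),
                                    strong_mult_unit("mult")),
                               seed = 32)
  cl <- classify_main(rec)
  expect_equal(cl[unit_id == "flat", main_label], "task_unrelated")
  expect_equal(cl[unit_id == "step", main_label], "action_related")
  expect_equal(cl[unit_id == "mult", main_label], "oma_selective")
  expect_equal(cl[unit_id == "step", selective_formats], "")
  ## strongly tuned everywhere -> selective in all four formats
  expect_equal(length(strsplit(cl[unit_id == "mult", selective_formats],
                               ",")[[1]]), 4)
})

test_that("epoch-modulated but untuned units are action-related across seeds", {
  ## rate doubles during the video for all exemplars equally: the epoch
  ## factor should fire, the exemplar factor should not (in most seeds)
  labels <- vapply(1:40, function(s) {
    rec <- generate_main_dataset(list(step_unit(step = 10)), seed = 4000 + s)
    classify_main(rec)$main_label
  }, "")
  expect_gte(mean(labels %in% c("action_related", "oma_selective")), 0.95)
  ## exemplar false positives across 4 formats x 2 effects promote
  ## ~1 - 0.95^8 = 34% of seeds to oma_selective by chance, so the exact
  ## action_related label is expected in roughly two thirds of seeds
  expect_gte(mean(labels == "action_related"), 0.5)
})

test_that("zero-variance units are classified without an ANOVA", {
  rec <- generate_main_dataset(list(flat_unit()), seed = 2)
  rec$spikes <- rec$spikes[0]
  expect_message(cl <- classify_main(rec), "zero variance")
  expect_equal(cl$main_label, "task_unrelated")
})

test_that("missing exemplar cells are rejected", {
  rec <- generate_main_dataset(list(strong_mult_unit()), seed = 3)
  drop <- rec$trials[exemplar == "drag" & format == "stand_lateral", trial_id]
  rec$trials <- rec$trials[!trial_id %in% drop]
  rec$spikes <- rec$spikes[!trial_id %in% drop]
  expect_error(classify_main(rec), "zero trials")
})

test_that("control classification separates unresponsive, related, selective", {
  ctl <- generate_control_dataset(
    list(flat_unit("null"), step_unit("resp", step = 10),
         strong_mult_unit("sel", baseline = 20,
                          tuning = seq(2, 44, by = 7))),
    seed = 41)
  cl <- classify_control(ctl$recordings)
  expect_equal(cl[unit_id == "null", control_label], "unresponsive")
  expect_equal(cl[unit_id == "resp", control_label], "video_related")
  expect_equal(cl[unit_id == "sel", control_label], "video_selective")
})

test_that("motion screen flags exact proportionality and strong coupling", {
  covs <- default_control_covariates()
  vm <- matrix(10 + 5 * covs$motion, nrow = 1,
               dimnames = list("prop", covs$video))
  scr <- motion_contrast_screen(vm, covs)
  expect_equal(scr$r_motion, 1, tolerance = 1e-12)
  expect_true(scr$excluded_for_motion)

  hits <- vapply(1:30, function(s) {
    ctl <- generate_control_dataset(
      list(unit_spec("mc", "motion_coupled", baseline_rate = 10,
                     motion_slope = 40)), seed = 7000 + s)
    motion_contrast_screen(video_epoch_means(ctl$recordings),
                           ctl$covariates)$excluded_for_motion
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("motion screen has nominal false-positive rate under the null", {
  ## rates independent of motion: exclusion rate ~ alpha
  covs <- default_control_covariates()
  set.seed(99)
  vm <- matrix(rnorm(1000 * 9, 10, 1), 1000, 9,
               dimnames = list(paste0("u", 1:1000), covs$video))
  scr <- motion_contrast_screen(vm, covs)
  fpr <- mean(scr$excluded_for_motion)
  expect_lt(abs(fpr - 0.05), 3 * sqrt(0.05 * 0.95 / 1000))
})

test_that("zero-variance rate rows are not excluded by the screen", {
  covs <- default_control_covariates()
  vm <- matrix(10, 1, 9, dimnames = list("z", covs$video))
  expect_message(scr <- motion_contrast_screen(vm, covs), "undefined")
  expect_false(scr$excluded_for_motion)
})

test_that("population video preference finds elevated videos", {
  covs <- default_control_covariates()
  set.seed(5)
  base <- matrix(rnorm(40 * 9, 10, 0.5), 40, 9,
                 dimnames = list(NULL, covs$video))
  ## identical expected means -> omnibus non-significant
  pref0 <- population_video_preference(base)
  expect_gt(pref0$omnibus_p, 0.05)
  ## one elevated video -> significant against all others
  up1 <- base; up1[, 3] <- up1[, 3] + 4
  pref1 <- population_video_preference(up1)
  expect_lt(pref1$omnibus_p, 0.05)
  v3 <- pref1$pairwise[video_a == covs$video[3] | video_b == covs$video[3]]
  expect_true(all(v3$significant))
  ## two elevated videos -> mutually indistinguishable, each above the rest
  up2 <- base; up2[, c(3, 5)] <- up2[, c(3, 5)] + 4
  pref2 <- population_video_preference(up2)
  pair35 <- pref2$pairwise[video_a == covs$video[3] & video_b == covs$video[5]]
  expect_false(pair35$significant)
  others <- pref2$pairwise[xor(video_a %in% covs$video[c(3, 5)],
                               video_b %in% covs$video[c(3, 5)])]
  expect_true(all(others$significant))
  expect_error(population_video_preference(base[1, , drop = FALSE]), "2 selective")
})

test_that("tuned-fraction time courses reflect the generative structure", {
  pop <- c(lapply(1:6, function(i) step_unit(paste0("f", i), step = 10)),
           lapply(1:6, function(i) {
             s <- strong_mult_unit(paste0("m", i))
             s
           }))
  ## give format_only units format-varying gains so viewpoint tuning exists
  pop[1:6] <- lapply(1:6, function(i)
    unit_spec(paste0("f", i), "format_only", baseline_rate = 10,
              format_gain = c(18, 16, 2, 3)))
  rec <- generate_main_dataset(pop, seed = 61)
  fv <- tuned_fraction_timecourse(rec, "viewpoint", window = c(-0.5, 2.0))
  fe <- tuned_fraction_timecourse(rec, "exemplar", window = c(-0.5, 2.0))
  pre <- fv$bin_start + 0.15 <= 0
  ## viewpoint tuning steps up right at onset (static format signal)
  expect_lt(mean(fv$fraction[pre]), 0.2)
  expect_gt(mean(fv$fraction[fv$bin_start >= 0 & fv$bin_start < 1.5]), 0.4)
  expect_true(any(fv$significant))
  ## exemplar tuning ramps: it reaches criterion later than viewpoint
  onset_v <- fv$bin_start[which(fv$significant)[1]]
  onset_e <- fe$bin_start[which(fe$significant)[1]]
  expect_gt(onset_e, onset_v)
  expect_error(tuned_fraction_timecourse(rec, "viewpoint", window = c(0.1, 1)),
               "baseline")
})
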