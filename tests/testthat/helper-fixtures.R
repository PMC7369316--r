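## Shared fixture builders. Everything is generated in code at test time;
## expensive recordings are built once per file and reused.

## A strongly tuned multiplicative unit: large rate separation between
## exemplars, identical ranking in every format by construction.
strong_mult_unit <- function(id = "m1", baseline = 40,
                             gains = c(1, 2, 1, 1),
                             tuning = seq(2, 44, by = 7)) {
  unit_spec(id, "multiplicative_stable", baseline_rate = baseline,
            exemplar_tuning = tuning, format_gain = gains)
}

flat_unit <- function(id = "u0", baseline = 10) {
  unit_spec(id, "untuned", baseline_rate = baseline)
}

## Rate step during the whole video, identical for every exemplar.
step_unit <- function(id = "s1", baseline = 10, step = 10) {
  unit_spec(id, "format_only", baseline_rate = baseline,
            format_gain = rep(step, 4))
}

mixed_unit <- function(id = "x1", baseline = 10, seed = 1) {
  pf <- with_seed(seed, matrix(rgamma(28, shape = 2, scale = 6), 4, 7))
  pf <- pf + pmax(0, apply(pf, 1, function(r) mean(r) - 2 * min(r) - baseline))
  unit_spec(id, "mixed_unstable", baseline_rate = baseline,
            per_format_tuning = pf)
}

## Minimal hand-built recording set with explicit spikes (deterministic).
manual_recording <- function(spikes, n_trials = 1, design = NULL) {
  trials <- data.table::CJ(exemplar = OMA_EXEMPLARS, format = OMA_FORMATS,
                           actor = "f", object = "a", repetition = 1,
                           sorted = TRUE)[1:n_trials]
  trials[, trial_id := seq_len(.N)]
  fmt <- OMA_FORMAT_TABLE
  trials[, posture := fmt$posture[match(format, fmt$format)]]
  trials[, viewpoint := fmt$viewpoint[match(format, fmt$format)]]
  new_recording_set(
    units = data.table::data.table(unit_id = unique(spikes$unit_id),
                                   unit_label = "single"),
    trials = trials, spikes = spikes,
    design = design %||% list(baseline_window = 0.5, video_duration = 2.6,
                              experiment = "main"))
}

## Deterministic full-design recording: one spike train per trial with a
## constant rate encoded as regularly spaced spikes (no Poisson noise).
## rate_fun(exemplar_index, format_index) -> spikes/s during the video.
regular_rate_recording <- function(rate_fun, baseline = 4, n_rep = 1) {
  trials <- data.table::CJ(exemplar = OMA_EXEMPLARS, format = OMA_FORMATS,
                           actor = "f", object = "a",
                           repetition = seq_len(n_rep), sorted = TRUE)
  trials[, trial_id := seq_len(.N)]
  fmt <- OMA_FORMAT_TABLE
  trials[, posture := fmt$posture[match(format, fmt$format)]]
  trials[, viewpoint := fmt$viewpoint[match(format, fmt$format)]]
  sp <- lapply(seq_len(nrow(trials)), function(i) {
    ei <- match(trials$exemplar[i], OMA_EXEMPLARS)
    fi <- match(trials$format[i], OMA_FORMATS)
    r <- rate_fun(ei, fi)
    ts <- c(seq(-0.5 + 1 / (2 * baseline), 0, by = 1 / baseline),
            if (r > 0) seq(1 / (2 * r), 2.6, by = 1 / r))
    data.table::data.table(unit_id = "r1", trial_id = trials$trial_id[i],
                           t = ts[ts < 2.6 & ts >= -0.5])
  })
  new_recording_set(
    units = data.table::data.table(unit_id = "r1", unit_label = "single"),
    trials = trials, spikes = data.table::rbindlist(sp),
    design = list(baseline_window = 0.5, video_duration = 2.6,
                  experiment = "main"))
}

## Brute-force UPGMA oracle: exhaustive average-linkage agglomeration.
upgma_oracle <- function(D) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  active <- rep(TRUE, n + (n - 1))
  heights <- numeric(n - 1)
  members <- c(as.list(seq_len(n)), vector("list", n - 1))
  avg_d <- function(a, b) mean(D[members[[a]], members[[b]]])
  ids <- seq_len(n)
  for (step in seq_len(n - 1)) {
    best <- Inf; pick <- c(NA, NA)
    for (i in seq_along(ids)) for (j in seq_len(i - 1)) {
      d <- avg_d(ids[i], ids[j])
      if (d < best - 1e-12) { best <- d; pick <- c(ids[j], ids[i]) }
    }
    new_id <- n + step
    members[[new_id]] <- c(members[[pick[1]]], members[[pick[2]]])
    heights[step] <- best
    ids <- c(setdiff(ids, pick), new_id)
  }
  sort(heights)
}
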