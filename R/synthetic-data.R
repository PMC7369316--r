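## Synthetic spike-data generator.
##
## Emulates a session of the 7-exemplar x 4-format observation design:
## 7 OMAs x 4 formats x 2 actors x 2 objects x 3 repetitions = 336 trials,
## 500 ms pre-onset baseline, 2.6-s videos; plus a 9-video natural-scene
## control session (3.5-s videos, 10 trials each) with per-video motion and
## contrast covariates. Spiking is an inhomogeneous Poisson process whose
## rate is piecewise linear in time: baseline before onset, a format-driven
## static step at video onset, and an exemplar-driven dynamic component that
## ramps from 300 ms to the end of epoch 2 (1.5 s) and is sustained to video
## end. Expected epoch-2 rates match the unit's tuning model exactly, so all
## downstream analyses can be checked against ground truth.

#' Unit archetype specification
#'
#' Defines the generative tuning model of one synthetic unit. The epoch-2
#' expected rate for exemplar i in format j is, by class:
#' \describe{
#'   \item{multiplicative_stable}{baseline + gain_j * tuning_i — a pure
#'     gain rescaling across formats, so the exemplar ranking is identical
#'     in every format.}
#'   \item{additive}{baseline + gain_j + tuning_i.}
#'   \item{mixed_unstable}{baseline + per_format_tuning[j, i], rows drawn
#'     independently: no cross-format rank relation.}
#'   \item{format_only}{baseline + gain_j (no exemplar information).}
#'   \item{untuned}{baseline in every condition.}
#'   \item{motion_coupled}{control experiment only: video-epoch rate
#'     baseline + motion_slope * motion covariate of the video.}
#' }
#'
#' @param unit_id unique identifier (string or integer).
#' @param unit_class one of `"multiplicative_stable"`, `"additive"`,
#'   `"mixed_unstable"`, `"format_only"`, `"untuned"`, `"motion_coupled"`.
#' @param baseline_rate baseline firing rate, spikes/s, >= 0.
#' @param exemplar_tuning 7 nonnegative weights (per OMA exemplar).
#' @param format_gain 4 positive gains (per format, order [OMA_FORMATS]).
#' @param per_format_tuning 4 x 7 nonnegative matrix (mixed_unstable only).
#' @param motion_slope spikes/s per unit of normalized motion
#'   (motion_coupled only).
#' @param noise_overlap `"single"` or `"multi"` — isolation label only.
#' @return an object of class `unit_spec`.
#' @export
unit_spec <- function(unit_id, unit_class,
                      baseline_rate = 10,
                      exemplar_tuning = NULL,
                      format_gain = NULL,
                      per_format_tuning = NULL,
                      motion_slope = 0,
                      noise_overlap = c("single", "multi")) {
  unit_class <- match.arg(unit_class, c(
    "multiplicative_stable", "additive", "mixed_unstable",
    "format_only", "untuned", "motion_coupled"))
  noise_overlap <- match.arg(noise_overlap)
  stop_if_not_scalar_number(baseline_rate, "baseline_rate")
  if (baseline_rate < 0) stop("baseline_rate must be >= 0")

  if (unit_class %in% c("multiplicative_stable", "additive")) {
    if (is.null(exemplar_tuning) || length(exemplar_tuning) != 7L ||
        any(!is.finite(exemplar_tuning)) || any(exemplar_tuning < 0))
      stop("exemplar_tuning must be 7 nonnegative finite weights")
  }
  if (unit_class %in% c("multiplicative_stable", "additive", "format_only")) {
    if (is.null(format_gain) || length(format_gain) != 4L ||
        any(!is.finite(format_gain)) || any(format_gain <= 0))
      stop("format_gain must be 4 positive finite gains")
  }
  if (unit_class == "mixed_unstable") {
    if (is.null(per_format_tuning) || !is.matrix(per_format_tuning) ||
        !all(dim(per_format_tuning) == c(4L, 7L)) ||
        any(!is.finite(per_format_tuning)) || any(per_format_tuning < 0))
      stop("per_format_tuning must be a 4 x 7 nonnegative matrix")
  }
  structure(list(
    unit_id = as.character(unit_id),
    unit_class = unit_class,
    baseline_rate = baseline_rate,
    exemplar_tuning = exemplar_tuning,
    format_gain = format_gain,
    per_format_tuning = per_format_tuning,
    motion_slope = motion_slope,
    noise_overlap = noise_overlap
  ), class = "unit_spec")
}

#' @export
print.unit_spec <- function(x, ...) {
  cat(sprintf("<unit_spec %s: %s, baseline %.1f sp/s>\n",
              x$unit_id, x$unit_class, x$baseline_rate))
  invisible(x)
}

#' Expected epoch-2 rate matrix of a unit (4 formats x 7 exemplars)
#'
#' @param spec a [unit_spec()].
#' @return 4 x 7 numeric matrix of expected firing rates (spikes/s) in
#'   epoch 2, rows = formats, columns = exemplars.
#' @export
expected_rate_matrix <- function(spec) {
  stopifnot(inherits(spec, "unit_spec"))
  b <- spec$baseline_rate
  m <- switch(spec$unit_class,
    multiplicative_stable = b + outer(spec$format_gain, spec$exemplar_tuning),
    additive      = b + outer(spec$format_gain, spec$exemplar_tuning, `+`),
    mixed_unstable = b + spec$per_format_tuning,
    format_only   = matrix(b + spec$format_gain, 4, 7),
    untuned       = matrix(b, 4, 7),
    motion_coupled = matrix(b, 4, 7)
  )
  dimnames(m) <- list(OMA_FORMATS, OMA_EXEMPLARS)
  m
}

## Format-driven static level during epoch 1 (exemplar-independent).
epoch1_levels <- function(spec) {
  b <- spec$baseline_rate
  lv <- switch(spec$unit_class,
    multiplicative_stable = b + spec$format_gain * mean(spec$exemplar_tuning),
    additive      = b + spec$format_gain,
    mixed_unstable = b + rowMeans(spec$per_format_tuning),
    format_only   = b + spec$format_gain,
    untuned       = rep(b, 4),
    motion_coupled = rep(b, 4)
  )
  setNames(lv, OMA_FORMATS)
}

#' Session design specification
#'
#' Constants of the observation paradigm: the main session presents each of
#' the 7 x 4 x 2 x 2 = 112 distinct videos 3 times (336 trials, 12 per
#' exemplar x format cell); the control session presents 9 natural videos
#' 10 times each.
#'
#' @param n_repetitions presentations of each distinct video (main), 3.
#' @param baseline_window pre-onset baseline duration, s.
#' @param video_duration main-experiment video duration, s.
#' @param control_video_duration control video duration, s.
#' @param n_control_videos number of natural control videos.
#' @param control_trials_per_video trials per control video.
#' @param jitter_frac SD of the zero-mean actor/object rate jitter, as a
#'   fraction of the unit's tuning amplitude.
#' @return an object of class `design_spec`.
#' @export
design_spec <- function(n_repetitions = 3,
                        baseline_window = 0.5,
                        video_duration = 2.6,
                        control_video_duration = 3.5,
                        n_control_videos = 9,
                        control_trials_per_video = 10,
                        jitter_frac = 0.05) {
  stop_if_not_scalar_number(baseline_window, "baseline_window", positive = TRUE)
  stop_if_not_scalar_number(video_duration, "video_duration", positive = TRUE)
  structure(list(
    n_exemplars = 7L, n_formats = 4L, n_actors = 2L, n_objects = 2L,
    n_repetitions = as.integer(n_repetitions),
    baseline_window = baseline_window,
    video_duration = video_duration,
    control_video_duration = control_video_duration,
    n_control_videos = as.integer(n_control_videos),
    control_trials_per_video = as.integer(control_trials_per_video),
    jitter_frac = jitter_frac
  ), class = "design_spec")
}

#' Number of distinct videos / presentations in a main session
#' @param design a [design_spec()].
#' @return named list with `n_distinct_videos`, `n_trials`,
#'   `trials_per_cell` (trials per exemplar x format cell).
#' @export
design_counts <- function(design = design_spec()) {
  nd <- design$n_exemplars * design$n_formats * design$n_actors * design$n_objects
  list(
    n_distinct_videos = nd,
    n_trials = nd * design$n_repetitions,
    trials_per_cell = design$n_actors * design$n_objects * design$n_repetitions
  )
}

## ---- Poisson sampling over piecewise-linear rate segments -------------

## Draw spike times for one linear-rate segment across many trials at once.
## a, p: start/end rates per trial (sp/s); t0, T: segment start and length.
## Exact inhomogeneous Poisson sampling: counts ~ Poisson(T(a+p)/2), times
## by inverse-CDF of the linear density.
sample_segment <- function(trial_id, a, p, t0, T) {
  a <- pmax(a, 0); p <- pmax(p, 0)
  mass <- T * (a + p) / 2
  n <- rpois(length(mass), mass)
  tot <- sum(n)
  if (tot == 0L)
    return(data.table(trial_id = integer(), t = numeric()))
  idx <- rep.int(seq_along(n), n)
  u <- runif(tot)
  A <- a[idx]; P <- p[idx]
  x <- numeric(tot)
  lin <- abs(P - A) > 1e-12
  if (any(!lin)) x[!lin] <- u[!lin] * T
  if (any(lin)) {
    Al <- A[lin]; Pl <- P[lin]; ul <- u[lin]
    q <- (Pl - Al) / (2 * T)
    disc <- Al^2 + ul * (Pl^2 - Al^2)
    x[lin] <- (-Al + sqrt(pmax(disc, 0))) / (2 * q)
  }
  data.table(trial_id = trial_id[idx], t = t0 + pmin(pmax(x, 0), T))
}

## ---- Main experiment ---------------------------------------------------

#' Generate a synthetic main-experiment session
#'
#' Draws trial-aligned spike timestamps for a population of synthetic units
#' over the full factorial design (7 exemplars x 4 formats x 2 actors x
#' 2 objects x 3 repetitions = 336 trials, presentation order randomized).
#' Per trial the firing rate is: baseline during `[-0.5, 0)` s; a static,
#' format-dependent level during `[0, 0.3)` s; a linear ramp from that level
#' to a peak over `[0.3, 1.5)` s chosen so the epoch-2 time-average equals
#' the unit's expected rate matrix; and the peak sustained to video end.
#' Actor and object add a small zero-mean rate jitter during the video.
#'
#' @param population list of [unit_spec()] objects.
#' @param design a [design_spec()].
#' @param seed master seed; identical seeds give identical output. Each
#'   unit draws from its own substream, so a subset of units regenerates
#'   identically regardless of the others.
#' @return an object of class `recording_set` with elements `units`,
#'   `trials`, `spikes` (data.tables), `design`, `ground_truth`.
#' @export
generate_main_dataset <- function(population, design = design_spec(), seed) {
  stopifnot(is.list(population), length(population) > 0)
  if (missing(seed)) stop("a seed is required")
  lapply(population, function(s) {
    if (!inherits(s, "unit_spec")) stop("population must be a list of unit_spec")
  })
  ids <- vapply(population, `[[`, "", "unit_id")
  if (anyDuplicated(ids)) stop("unit ids must be unique")

  trials <- CJ(exemplar = OMA_EXEMPLARS, format = OMA_FORMATS,
               actor = c("f", "m"), object = c("a", "b"),
               repetition = seq_len(design$n_repetitions), sorted = TRUE)
  nct <- design_counts(design)
  stopifnot(nrow(trials) == nct$n_trials)
  ord <- with_seed(substream_seed(seed, 0L), sample.int(nrow(trials)))
  trials <- trials[ord]
  trials[, trial_id := seq_len(.N)]
  fmt_tab <- OMA_FORMAT_TABLE
  trials[, posture := fmt_tab$posture[match(format, fmt_tab$format)]]
  trials[, viewpoint := fmt_tab$viewpoint[match(format, fmt_tab$format)]]
  setcolorder(trials, c("trial_id", "exemplar", "format", "posture",
                        "viewpoint", "actor", "object", "repetition"))

  bw <- design$baseline_window
  vd <- design$video_duration
  e2_end <- 1.5

  spk <- vector("list", length(population))
  for (k in seq_along(population)) {
    spec <- population[[k]]
    if (spec$unit_class == "motion_coupled")
      stop("motion_coupled units belong to the control experiment")
    mu <- expected_rate_matrix(spec)          # 4 x 7 epoch-2 expectations
    a_lv <- epoch1_levels(spec)               # per-format static level
    peak <- 2 * mu - matrix(a_lv, 4, 7)       # ramp endpoint at 1.5 s
    if (any(peak < -1e-9))
      stop(sprintf("unit %s: negative expected rate in ramp (spec rejected)",
                   spec$unit_id))
    peak <- pmax(peak, 0)

    spk[[k]] <- with_seed(substream_seed(seed, k), {
      amp <- max(mu) - min(mu)
      raw <- rnorm(4L)
      raw <- raw - mean(raw)                  # exactly zero-mean
      ## scale to the target SD, shrunk so no video-segment rate can go
      ## negative (clamping would bias the condition means)
      lo <- min(a_lv, peak)
      sc <- if (max(abs(raw)) > 0)
        min(design$jitter_frac * amp / max(sd(raw), 1e-12),
            0.95 * lo / max(abs(raw))) else 0
      jit4 <- raw * max(sc, 0)
      jkey <- paste(rep(c("f", "m"), each = 2), c("a", "b"))
      jit <- setNames(jit4, jkey)

      fi <- match(trials$format, OMA_FORMATS)
      ei <- match(trials$exemplar, OMA_EXEMPLARS)
      jt <- jit[paste(trials$actor, trials$object)]
      a_t <- a_lv[fi] + jt
      p_t <- peak[cbind(fi, ei)] + jt
      tid <- trials$trial_id

      out <- rbindlist(list(
        sample_segment(tid, rep(spec$baseline_rate, length(tid)),
                       rep(spec$baseline_rate, length(tid)), -bw, bw),
        sample_segment(tid, a_t, a_t, 0, 0.3),
        sample_segment(tid, a_t, p_t, 0.3, e2_end - 0.3),
        sample_segment(tid, p_t, p_t, e2_end, vd - e2_end)
      ))
      out[, unit_id := spec$unit_id]
      out
    })
  }
  spikes <- rbindlist(spk)
  setcolorder(spikes, c("unit_id", "trial_id", "t"))
  setkey(spikes, unit_id, trial_id, t)

  units <- data.table(
    unit_id = ids,
    unit_label = vapply(population, `[[`, "", "noise_overlap")
  )
  gt <- data.table(
    unit_id = ids,
    unit_class = vapply(population, `[[`, "", "unit_class"),
    baseline_rate = vapply(population, `[[`, 0, "baseline_rate")
  )
  new_recording_set(units, trials, spikes,
                    design = list(baseline_window = bw, video_duration = vd,
                                  experiment = "main"),
                    ground_truth = gt, population = population)
}

## ---- Control experiment ------------------------------------------------

#' Default motion / contrast covariates for the 9 natural control videos
#'
#' Fixed normalized covariates (0-1 scale) for the nine natural dynamic
#' scenes: high motion for the manipulative and fast-moving-animal videos,
#' near-zero for the resting monkey and static landscape pan.
#' @return data.table with `video`, `motion`, `contrast`.
#' @export
default_control_covariates <- function() {
  data.table(
    video = paste0("v", 1:9),
    label = c("grasp", "groom", "lipsmack", "scream", "yawn",
              "chew", "rest", "crab", "landscape"),
    motion   = c(0.72, 0.41, 0.33, 0.58, 0.26, 0.22, 0.06, 0.81, 0.12),
    contrast = c(0.55, 0.38, 0.46, 0.62, 0.41, 0.35, 0.30, 0.52, 0.67)
  )
}

#' Generate a synthetic control-experiment session (natural videos)
#'
#' Nine natural videos, 10 trials each, 3.5-s duration, 0.5-s baseline.
#' `motion_coupled` units fire at baseline + motion_slope x motion covariate
#' during the video; other unit classes receive a per-video effect derived
#' from their main-experiment tuning (recycled over the nine videos) so the
#' same archetypes remain responsive / selective in the control screen;
#' `untuned` units stay at baseline.
#'
#' @inheritParams generate_main_dataset
#' @param covariates per-video motion/contrast table, as
#'   [default_control_covariates()].
#' @return list with `recordings` (a `recording_set`, trials labelled by
#'   `video`) and `covariates`.
#' @export
generate_control_dataset <- function(population, design = design_spec(), seed,
                                     covariates = default_control_covariates()) {
  stopifnot(is.list(population), length(population) > 0)
  if (missing(seed)) stop("a seed is required")
  covariates <- as.data.table(covariates)
  if (nrow(covariates) != design$n_control_videos)
    stop("covariates must have one row per control video")
  if (!all(c("video", "motion", "contrast") %in% names(covariates)))
    stop("covariates must have columns video, motion, contrast")

  nv <- design$n_control_videos
  trials <- CJ(video = covariates$video,
               repetition = seq_len(design$control_trials_per_video),
               sorted = TRUE)
  ord <- with_seed(substream_seed(seed, 0L, 999L), sample.int(nrow(trials)))
  trials <- trials[ord]
  trials[, trial_id := seq_len(.N)]
  setcolorder(trials, c("trial_id", "video", "repetition"))

  bw <- design$baseline_window
  vd <- design$control_video_duration
  ids <- vapply(population, `[[`, "", "unit_id")
  if (anyDuplicated(ids)) stop("unit ids must be unique")

  spk <- vector("list", length(population))
  for (k in seq_along(population)) {
    spec <- population[[k]]
    eff <- control_video_effects(spec, covariates)
    if (any(spec$baseline_rate + eff < -1e-9))
      stop(sprintf("unit %s: negative expected control rate", spec$unit_id))
    spk[[k]] <- with_seed(substream_seed(seed, k, 999L), {
      vi <- match(trials$video, covariates$video)
      r_vid <- pmax(spec$baseline_rate + eff[vi], 0)
      tid <- trials$trial_id
      out <- rbindlist(list(
        sample_segment(tid, rep(spec$baseline_rate, length(tid)),
                       rep(spec$baseline_rate, length(tid)), -bw, bw),
        sample_segment(tid, r_vid, r_vid, 0, vd)
      ))
      out[, unit_id := spec$unit_id]
      out
    })
  }
  spikes <- rbindlist(spk)
  setcolorder(spikes, c("unit_id", "trial_id", "t"))
  setkey(spikes, unit_id, trial_id, t)

  units <- data.table(unit_id = ids,
                      unit_label = vapply(population, `[[`, "", "noise_overlap"))
  gt <- data.table(unit_id = ids,
                   unit_class = vapply(population, `[[`, "", "unit_class"),
                   baseline_rate = vapply(population, `[[`, 0, "baseline_rate"))
  rec <- new_recording_set(units, trials, spikes,
                           design = list(baseline_window = bw,
                                         video_duration = vd,
                                         experiment = "control"),
                           ground_truth = gt, population = population)
  list(recordings = rec, covariates = covariates)
}

## Per-video additive rate effect (sp/s) in the control experiment.
control_video_effects <- function(spec, covariates) {
  nv <- nrow(covariates)
  rec7 <- function(x) x[((seq_len(nv) - 1L) %% 7L) + 1L]
  switch(spec$unit_class,
    motion_coupled = spec$motion_slope * covariates$motion,
    untuned = rep(0, nv),
    format_only = rep(mean(spec$format_gain), nv),
    multiplicative_stable = mean(spec$format_gain) * rec7(spec$exemplar_tuning),
    additive = mean(spec$format_gain) + rec7(spec$exemplar_tuning),
    mixed_unstable = rec7(colMeans(spec$per_format_tuning))
  )
}

## ---- Default population sampler ---------------------------------------

#' Sample a population of synthetic unit specifications
#'
#' Draws unit archetypes with realistic firing parameters: baselines
#' uniform on 5-15 sp/s, gamma-distributed exemplar tuning with ~10 sp/s
#' mean drive, and log-normal format gains (SD 0.35 on the log scale,
#' clipped to [0.4, 2.5]) mimicking across-format rate rescaling. Tuning
#' vectors are shifted where needed so every ramp endpoint stays
#' nonnegative (a validity requirement of the generative model).
#'
#' @param n_units number of units.
#' @param class_mix named numeric vector of class proportions (or counts);
#'   names are `unit_spec` classes.
#' @param seed master seed.
#' @param motion_slope slope for any `motion_coupled` units, sp/s per
#'   normalized motion unit.
#' @return list of [unit_spec()].
#' @export
sample_population <- function(n_units,
                              class_mix = c(multiplicative_stable = 0.3,
                                            additive = 0.2,
                                            mixed_unstable = 0.2,
                                            format_only = 0.1,
                                            untuned = 0.2),
                              seed,
                              motion_slope = 20) {
  if (missing(seed)) stop("a seed is required")
  stopifnot(n_units >= 1, all(class_mix >= 0), sum(class_mix) > 0)
  counts <- round(class_mix / sum(class_mix) * n_units)
  while (sum(counts) > n_units) counts[which.max(counts)] <- counts[which.max(counts)] - 1L
  while (sum(counts) < n_units) counts[which.min(counts)] <- counts[which.min(counts)] + 1L
  classes <- rep(names(counts), counts)

  lapply(seq_len(n_units), function(k) {
    with_seed(substream_seed(seed, k, 777L), {
      cls <- classes[k]
      b <- runif(1, 5, 15)
      gain <- pmin(pmax(exp(rnorm(4, 0, 0.35)), 0.4), 2.5)
      tun <- rgamma(7, shape = 2, scale = 5)
      ## keep ramp endpoints nonnegative: need min(tun) >= mean(tun)/2
      shift <- max(0, mean(tun) - 2 * min(tun))
      tun_safe <- tun + shift
      switch(cls,
        multiplicative_stable = unit_spec(k, cls, b,
          exemplar_tuning = tun_safe, format_gain = gain),
        additive = unit_spec(k, cls, b,
          ## gain and tuning drives on a common scale: class differences
          ## should reflect the mixing rule, not drive strength
          exemplar_tuning = runif(7, 0, 20), format_gain = runif(4, 0.5, 20)),
        mixed_unstable = {
          pf <- matrix(rgamma(28, shape = 2, scale = 5), 4, 7)
          pf <- pf + pmax(0, apply(pf, 1, function(r) mean(r) - 2 * min(r) - b))
          unit_spec(k, cls, b, per_format_tuning = pf)
        },
        format_only = unit_spec(k, cls, b, format_gain = runif(4, 2, 10)),
        untuned = unit_spec(k, cls, b),
        motion_coupled = unit_spec(k, cls, b, motion_slope = motion_slope)
      )
    })
  })
}
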