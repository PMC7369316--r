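## Data model and I/O: trial-aligned spike tables, epoching, binning,
## population net activity. Time is in seconds, double precision, video
## onset = 0; bins are half-open [start, start + width) and reported at the
## start of their interval.

#' Construct a recording set
#'
#' The universal input of the pipeline: a unit table, a trial table with
#' condition labels, and a spike table of timestamps relative to video
#' onset.
#'
#' @param units data.frame with `unit_id` (unique) and `unit_label`
#'   (`"single"`/`"multi"`).
#' @param trials data.frame with `trial_id` (unique) and condition labels.
#' @param spikes data.frame with `unit_id`, `trial_id`, `t` (seconds).
#' @param design list with at least `baseline_window`, `video_duration`,
#'   `experiment`.
#' @param ground_truth optional per-unit generative labels (synthetic data).
#' @param population optional list of [unit_spec()] used to generate the set.
#' @return object of class `recording_set`.
#' @export
new_recording_set <- function(units, trials, spikes, design,
                              ground_truth = NULL, population = NULL) {
  units <- as.data.table(units); trials <- as.data.table(trials)
  spikes <- as.data.table(spikes)
  if (anyDuplicated(units$unit_id)) stop("unit ids must be unique")
  if (anyDuplicated(trials$trial_id)) stop("trial ids must be unique")
  need <- switch(design$experiment %||% "main",
                 main = c("exemplar", "format", "posture", "viewpoint",
                          "actor", "object", "repetition"),
                 control = c("video", "repetition"))
  miss <- setdiff(need, names(trials))
  if (length(miss))
    stop("trials table lacks condition labels: ", paste(miss, collapse = ", "))
  if (nrow(spikes)) {
    if (!all(spikes$unit_id %in% units$unit_id)) stop("spikes reference unknown units")
    lo <- -design$baseline_window - 1e-9
    hi <- design$video_duration + 1e-9
    if (any(spikes$t < lo | spikes$t > hi))
      stop("spike timestamps outside [-baseline_window, video_duration]")
  }
  structure(list(units = units, trials = trials, spikes = spikes,
                 design = design, ground_truth = ground_truth,
                 population = population),
            class = "recording_set")
}

#' @export
print.recording_set <- function(x, ...) {
  cat(sprintf("<recording_set [%s]: %d units, %d trials, %d spikes>\n",
              x$design$experiment, nrow(x$units), nrow(x$trials),
              nrow(x$spikes)))
  invisible(x)
}

#' Canonical epoch windows (seconds, half-open)
#'
#' Baseline `[-0.5, 0)`; epoch 1 `[0, 0.3)` (static posture information);
#' epoch 2 `[0.3, 1.5)` (dynamic action information, exactly 1.2 s);
#' control video epoch `[0.5, 3.0)`.
#' @return named list of 2-vectors.
#' @export
epoch_windows <- function() {
  list(baseline = c(-0.5, 0), epoch1 = c(0, 0.3), epoch2 = c(0.3, 1.5),
       control_video = c(0.5, 3.0))
}

## ---- File I/O ----------------------------------------------------------

#' Write / read a recording set as plain-text columnar tables
#'
#' Writes `units.csv`, `trials.csv`, `spikes.csv`, a `design.dcf` config
#' and, for synthetic data, a `ground_truth.csv` sidecar.
#'
#' @param rec a `recording_set`.
#' @param dir target directory (created if needed).
#' @return `write_recording_set`: the directory, invisibly.
#'   `read_recording_set`: the `recording_set`.
#' @export
write_recording_set <- function(rec, dir) {
  stopifnot(inherits(rec, "recording_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fwrite(rec$units, file.path(dir, "units.csv"))
  fwrite(rec$trials, file.path(dir, "trials.csv"))
  fwrite(rec$spikes, file.path(dir, "spikes.csv"))
  dsn <- rec$design
  write.dcf(as.data.frame(dsn, stringsAsFactors = FALSE),
            file.path(dir, "design.dcf"))
  if (!is.null(rec$ground_truth))
    fwrite(rec$ground_truth, file.path(dir, "ground_truth.csv"))
  invisible(dir)
}

#' @rdname write_recording_set
#' @export
read_recording_set <- function(dir) {
  dsn <- as.list(as.data.frame(read.dcf(file.path(dir, "design.dcf")),
                               stringsAsFactors = FALSE))
  dsn$baseline_window <- as.numeric(dsn$baseline_window)
  dsn$video_duration <- as.numeric(dsn$video_duration)
  gt_path <- file.path(dir, "ground_truth.csv")
  new_recording_set(
    units = fread(file.path(dir, "units.csv"), colClasses = list(character = "unit_id")),
    trials = fread(file.path(dir, "trials.csv")),
    spikes = fread(file.path(dir, "spikes.csv"), colClasses = list(character = "unit_id")),
    design = dsn,
    ground_truth = if (file.exists(gt_path))
      fread(gt_path, colClasses = list(character = "unit_id")) else NULL
  )
}

## ---- Binning -----------------------------------------------------------

bin_starts_for <- function(window, width, step) {
  s <- seq(window[1], window[2], by = step)
  s[s + width <= window[2] + 1e-9]
}

## counts[u, tr, k] of spikes in [s_k, s_k + width), all units x trials.
## Sliding windows may overlap, so each bin is counted as the difference of
## two cumulative counts on the sorted per-trial spike train.
count_tensor <- function(rec, width, step, window) {
  starts <- bin_starts_for(window, width, step)
  if (!length(starts)) stop("empty window: no bin fits inside it")
  uid <- rec$units$unit_id
  tid <- rec$trials$trial_id
  nb <- length(starts)
  cnt <- array(0L, dim = c(length(uid), length(tid), nb),
               dimnames = list(uid, NULL, NULL))
  sp <- rec$spikes
  if (nrow(sp)) {
    setkey(sp, unit_id, trial_id, t)
    grp <- sp[, .(ts = list(t)), by = .(unit_id, trial_id)]
    ui <- match(grp$unit_id, uid)
    ti <- match(grp$trial_id, tid)
    lo <- starts; hi <- starts + width - 1e-12
    for (g in seq_len(nrow(grp))) {
      ts <- grp$ts[[g]]
      cnt[ui[g], ti[g], ] <- findInterval(hi, ts) - findInterval(lo - 1e-12, ts)
    }
  }
  list(counts = cnt, starts = starts)
}

#' Bin spike trains into a unit x trial x time-bin rate tensor
#'
#' Rates are spike count in the half-open bin `[start, start + width)`
#' divided by the bin width; bins advance by `step` and partial bins beyond
#' the window are excluded. Each bin is referenced by its start time.
#'
#' @param rec a `recording_set`.
#' @param width bin width, s.
#' @param step bin step, s (a step larger than the width leaves gaps and is
#'   flagged with a message).
#' @param window 2-vector, analysis window in trial time.
#' @return object of class `binned_tensor`: list with `rates`
#'   (units x trials x bins array, spikes/s), `counts`, `bin_starts`,
#'   `bin_width_s`, `bin_step_s`, `trials` (the trial table).
#' @export
bin_rates <- function(rec, width, step, window) {
  stopifnot(inherits(rec, "recording_set"))
  stop_if_not_scalar_number(width, "width", positive = TRUE)
  stop_if_not_scalar_number(step, "step", positive = TRUE)
  if (window[2] <= window[1]) stop("empty window")
  if (step > width + 1e-12)
    message("bin step exceeds width: bins leave gaps in coverage")
  ct <- count_tensor(rec, width, step, window)
  structure(list(rates = ct$counts / width, counts = ct$counts,
                 bin_starts = ct$starts, bin_width_s = width,
                 bin_step_s = step, trials = rec$trials,
                 unit_ids = rec$units$unit_id),
            class = "binned_tensor")
}

#' @export
print.binned_tensor <- function(x, ...) {
  cat(sprintf("<binned_tensor: %d units x %d trials x %d bins (%.0f/%.0f ms)>\n",
              dim(x$rates)[1], dim(x$rates)[2], dim(x$rates)[3],
              x$bin_width_s * 1e3, x$bin_step_s * 1e3))
  invisible(x)
}

#' Per-trial firing rates in named epochs
#'
#' One bin per epoch: rate = spike count in the epoch window / duration.
#'
#' @param rec a `recording_set`.
#' @param epochs named list of 2-vector windows, as [epoch_windows()].
#' @return long data.table: `unit_id`, `trial_id`, `epoch`, `rate`.
#' @export
epoch_rates <- function(rec, epochs = epoch_windows()[c("baseline", "epoch1", "epoch2")]) {
  stopifnot(inherits(rec, "recording_set"), length(epochs) >= 1)
  out <- vector("list", length(epochs))
  for (i in seq_along(epochs)) {
    w <- epochs[[i]]
    if (w[2] <= w[1]) stop("empty epoch window: ", names(epochs)[i])
    ct <- count_tensor(rec, width = w[2] - w[1], step = w[2] - w[1], window = w)
    cnt <- ct$counts[, , 1, drop = TRUE]
    if (is.null(dim(cnt))) cnt <- matrix(cnt, nrow = nrow(rec$units))
    dt <- data.table(
      unit_id = rep(rec$units$unit_id, times = nrow(rec$trials)),
      trial_id = rep(rec$trials$trial_id, each = nrow(rec$units)),
      epoch = names(epochs)[i],
      rate = as.vector(cnt) / (w[2] - w[1])
    )
    out[[i]] <- dt
  }
  rbindlist(out)
}

#' Baseline-subtracted net population activity
#'
#' For each unit the mean baseline rate is subtracted from every bin, then
#' bins are averaged across units; the default 60-ms/20-ms binning is the
#' standard population-plot resolution.
#'
#' @param binned a [bin_rates()] result whose window includes the baseline.
#' @param unit_subset unit ids to include (default all).
#' @param baseline_window 2-vector, window defining the baseline bins (bins
#'   entirely inside it).
#' @return data.table: `bin_start`, `net_mean` (spikes/s), `net_se`.
#' @export
net_population_activity <- function(binned, unit_subset = NULL,
                                    baseline_window = c(-0.5, 0)) {
  stopifnot(inherits(binned, "binned_tensor"))
  ids <- unit_subset %||% binned$unit_ids
  if (!length(ids)) stop("unit subset is empty")
  ki <- match(ids, binned$unit_ids)
  if (anyNA(ki)) stop("unknown unit ids in subset")
  bs <- binned$bin_starts
  base_bins <- which(bs >= baseline_window[1] - 1e-9 &
                     bs + binned$bin_width_s <= baseline_window[2] + 1e-9)
  if (!length(base_bins)) stop("no bins fall inside the baseline window")
  ## unit x bin mean over trials
  ub <- apply(binned$rates[ki, , , drop = FALSE], c(1, 3), mean)
  net <- ub - rowMeans(ub[, base_bins, drop = FALSE])
  data.table(bin_start = bs,
             net_mean = colMeans(net),
             net_se = apply(net, 2, sd) / sqrt(length(ki)))
}
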