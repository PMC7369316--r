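## ANOVA-based unit classification for the main (7 OMA x 4 format) and
## control (9 natural videos) experiments, the motion/contrast exclusion
## screen, and the time-resolved tuned-fraction analysis.
##
## The "repeated-measures" ANOVAs are realized as split-plot designs with
## trials as subjects: epoch is the within-trial factor (each trial yields a
## baseline, epoch-1 and epoch-2 rate) and exemplar/video the between-trial
## factor, fitted with aov() + Error(trial) strata.

## Extract p-values for the three effects of a split-plot aov summary.
split_plot_pvals <- function(fit) {
  sm <- summary(fit)
  ps <- c(between = NA_real_, within = NA_real_, interaction = NA_real_)
  for (stratum in sm) {
    tab <- stratum[[1]]
    rn <- trimws(rownames(tab))
    pv <- tab[["Pr(>F)"]]
    for (i in seq_along(rn)) {
      if (grepl(":", rn[i])) ps["interaction"] <- pv[i]
      else if (rn[i] == "epoch") ps["within"] <- pv[i]
      else if (rn[i] %in% c("exemplar", "video")) ps["between"] <- pv[i]
    }
  }
  ps
}

#' Classify units of the main experiment
#'
#' Per unit and per format, a 3 x 7 split-plot ANOVA (epoch within trial:
#' baseline / epoch 1 / epoch 2; exemplar between trials) is fitted on
#' per-trial epoch rates. A unit is `action_related` when the epoch factor
#' is significant (main or interaction, `P < alpha`) in at least one format
#' and a Bonferroni-corrected paired post hoc confirms that epoch 1 and/or
#' epoch 2 differs from baseline in such a format; `oma_selective` when, in
#' addition, the exemplar factor is significant (main or interaction) in at
#' least one format. Remaining units are `task_unrelated`. Zero-variance
#' units are labelled `task_unrelated` without an ANOVA.
#'
#' @param rec a main-experiment `recording_set`.
#' @param alpha significance level (default 0.05).
#' @return data.table, one row per unit: `main_label`, `selective_formats`
#'   (comma-separated), plus per-format p-values for the epoch effect
#'   (`p_epoch_*`), exemplar effect (`p_exemplar_*`), interaction
#'   (`p_interaction_*`) and post hoc gate (`posthoc_*`).
#' @export
classify_main <- function(rec, alpha = 0.05) {
  stopifnot(inherits(rec, "recording_set"))
  er <- epoch_rates(rec, epoch_windows()[c("baseline", "epoch1", "epoch2")])
  er <- merge(er, rec$trials[, .(trial_id, exemplar, format)], by = "trial_id")
  setkey(er, unit_id)

  rows <- lapply(rec$units$unit_id, function(u) {
    d <- er[.(u)]
    out <- list(unit_id = u)
    if (sd(d$rate) == 0) {
      message("unit ", u, ": zero variance, classified task_unrelated without ANOVA")
      out$main_label <- "task_unrelated"
      out$selective_formats <- ""
      return(as.data.table(out))
    }
    epoch_sig <- posthoc_sig <- exem_sig <- logical(4)
    for (j in seq_along(OMA_FORMATS)) {
      df <- d[format == OMA_FORMATS[j]]
      cells <- df[epoch == "epoch2", .N, by = exemplar]
      if (nrow(cells) < 7L || any(cells$N == 0))
        stop("unit ", u, ", format ", OMA_FORMATS[j],
             ": exemplar with zero trials")
      df[, `:=`(epoch = factor(epoch, c("baseline", "epoch1", "epoch2")),
                exemplar = factor(exemplar, OMA_EXEMPLARS),
                trial_f = factor(trial_id))]
      fit <- aov(rate ~ epoch * exemplar + Error(trial_f), data = df)
      ps <- split_plot_pvals(fit)
      out[[paste0("p_epoch_", j)]] <- ps[["within"]]
      out[[paste0("p_exemplar_", j)]] <- ps[["between"]]
      out[[paste0("p_interaction_", j)]] <- ps[["interaction"]]
      epoch_sig[j] <- isTRUE(ps[["within"]] < alpha) ||
                      isTRUE(ps[["interaction"]] < alpha)
      exem_sig[j] <- isTRUE(ps[["between"]] < alpha) ||
                     isTRUE(ps[["interaction"]] < alpha)
      ## Bonferroni post hoc: either epoch differs from baseline (paired)
      w <- dcast(df, trial_id ~ epoch, value.var = "rate")
      pp <- c(tryCatch(t.test(w$epoch1, w$baseline, paired = TRUE)$p.value,
                       error = function(e) NA_real_),
              tryCatch(t.test(w$epoch2, w$baseline, paired = TRUE)$p.value,
                       error = function(e) NA_real_))
      pp <- p.adjust(pp, method = "bonferroni")
      posthoc_sig[j] <- any(pp < alpha, na.rm = TRUE)
      out[[paste0("posthoc_", j)]] <- suppressWarnings(min(pp, na.rm = TRUE))
    }
    action <- any(epoch_sig & posthoc_sig)
    selective <- action && any(exem_sig)
    out$main_label <- if (selective) "oma_selective"
                      else if (action) "action_related" else "task_unrelated"
    out$selective_formats <- if (selective)
      paste(OMA_FORMATS[exem_sig], collapse = ",") else ""
    as.data.table(out)
  })
  rbindlist(rows, fill = TRUE)
}

#' Classify units of the control experiment
#'
#' Per unit, a 2 x 9 split-plot ANOVA (epoch within trial: baseline vs.
#' video epoch; video identity between trials) followed by a Fisher LSD
#' test (unadjusted paired comparison gated on the significant omnibus).
#' `video_related`: epoch effect significant (main or interaction) with the
#' LSD confirming the video epoch differs from baseline; `video_selective`:
#' additionally the video factor significant (main or interaction);
#' otherwise `unresponsive`.
#'
#' @param rec a control-experiment `recording_set`.
#' @param alpha significance level.
#' @return data.table: `unit_id`, `control_label`, p-values.
#' @export
classify_control <- function(rec, alpha = 0.05) {
  stopifnot(inherits(rec, "recording_set"),
            identical(rec$design$experiment, "control"))
  er <- epoch_rates(rec, epoch_windows()[c("baseline", "control_video")])
  er <- merge(er, rec$trials[, .(trial_id, video)], by = "trial_id")
  setkey(er, unit_id)
  rows <- lapply(rec$units$unit_id, function(u) {
    d <- er[.(u)]
    if (sd(d$rate) == 0) {
      message("unit ", u, ": zero variance, classified unresponsive without ANOVA")
      return(data.table(unit_id = u, control_label = "unresponsive",
                        p_epoch = NA_real_, p_video = NA_real_,
                        p_interaction = NA_real_, p_lsd = NA_real_))
    }
    d[, `:=`(epoch = factor(epoch, c("baseline", "control_video")),
             video = factor(video), trial_f = factor(trial_id))]
    fit <- aov(rate ~ epoch * video + Error(trial_f), data = d)
    ps <- split_plot_pvals(fit)
    omnibus <- isTRUE(ps[["within"]] < alpha) || isTRUE(ps[["interaction"]] < alpha)
    w <- dcast(d, trial_id ~ epoch, value.var = "rate")
    p_lsd <- tryCatch(t.test(w$control_video, w$baseline, paired = TRUE)$p.value,
                      error = function(e) NA_real_)
    related <- omnibus && isTRUE(p_lsd < alpha)
    selective <- related && (isTRUE(ps[["between"]] < alpha) ||
                             isTRUE(ps[["interaction"]] < alpha))
    data.table(unit_id = u,
               control_label = if (selective) "video_selective"
                               else if (related) "video_related" else "unresponsive",
               p_epoch = ps[["within"]], p_video = ps[["between"]],
               p_interaction = ps[["interaction"]], p_lsd = p_lsd)
  })
  rbindlist(rows)
}

#' Per-unit mean video-epoch rate for each control video
#'
#' @param rec a control `recording_set`.
#' @param window video-epoch window (default `[0.5, 3.0)` s).
#' @return matrix units x videos of mean rates (spikes/s).
#' @export
video_epoch_means <- function(rec, window = epoch_windows()$control_video) {
  er <- epoch_rates(rec, list(video_epoch = window))
  er <- merge(er, rec$trials[, .(trial_id, video)], by = "trial_id")
  m <- dcast(er[, .(rate = mean(rate)), by = .(unit_id, video)],
             unit_id ~ video, value.var = "rate")
  out <- as.matrix(m[, -1])
  rownames(out) <- m$unit_id
  out[match(rec$units$unit_id, rownames(out)), , drop = FALSE]
}

#' Motion / contrast exclusion screen
#'
#' Pearson correlation, across the nine control videos, between each unit's
#' mean video-epoch rate and the motion and contrast covariates. Units with
#' a significant motion correlation (`P < alpha`) are flagged for
#' exclusion; contrast is tested and reported identically. Zero-variance
#' rate profiles leave the correlation undefined and are not excluded.
#'
#' @param video_means units x 9 matrix as from [video_epoch_means()].
#' @param covariates covariate table with `motion` and `contrast`.
#' @param alpha significance level.
#' @return data.table: `unit_id`, `r_motion`, `p_motion`, `r_contrast`,
#'   `p_contrast`, `excluded_for_motion`, `excluded_for_contrast`.
#' @export
motion_contrast_screen <- function(video_means, covariates, alpha = 0.05) {
  covariates <- as.data.table(covariates)
  stopifnot(ncol(video_means) == nrow(covariates))
  one <- function(rates, cov) {
    if (sd(rates) == 0 || sd(cov) == 0) {
      message("zero-variance rates: correlation undefined, unit not excluded")
      return(c(NA_real_, NA_real_))
    }
    ct <- cor.test(rates, cov)
    c(unname(ct$estimate), ct$p.value)
  }
  rows <- lapply(seq_len(nrow(video_means)), function(i) {
    mo <- one(video_means[i, ], covariates$motion)
    co <- one(video_means[i, ], covariates$contrast)
    data.table(unit_id = rownames(video_means)[i],
               r_motion = mo[1], p_motion = mo[2],
               r_contrast = co[1], p_contrast = co[2],
               excluded_for_motion = isTRUE(mo[2] < alpha),
               excluded_for_contrast = isTRUE(co[2] < alpha))
  })
  rbindlist(rows)
}

#' Population-level video preference among selective units
#'
#' One-way repeated-measures ANOVA across the nine videos with units as the
#' repeated measures, followed by Bonferroni-corrected pairwise paired
#' comparisons.
#'
#' @param video_means units x videos matrix (selective units only).
#' @param alpha significance level for reporting.
#' @return list: `omnibus_p`, `video_means` (population mean per video),
#'   `pairwise` (data.table of Bonferroni-corrected paired t-tests).
#' @export
population_video_preference <- function(video_means, alpha = 0.05) {
  if (nrow(video_means) < 2L) stop("need at least 2 selective units")
  vids <- colnames(video_means) %||% paste0("v", seq_len(ncol(video_means)))
  long <- data.table(
    unit = factor(rep(seq_len(nrow(video_means)), times = ncol(video_means))),
    video = factor(rep(vids, each = nrow(video_means)), levels = vids),
    rate = as.vector(video_means))
  fit <- aov(rate ~ video + Error(unit), data = long)
  sm <- summary(fit)
  omnibus_p <- NA_real_
  for (stratum in sm) {
    tab <- stratum[[1]]
    i <- match("video", trimws(rownames(tab)))
    if (!is.na(i)) omnibus_p <- tab[["Pr(>F)"]][i]
  }
  prs <- combn(vids, 2, simplify = FALSE)
  pw <- rbindlist(lapply(prs, function(pr) {
    tt <- t.test(video_means[, pr[1]], video_means[, pr[2]], paired = TRUE)
    data.table(video_a = pr[1], video_b = pr[2], p_raw = tt$p.value)
  }))
  pw[, p_bonf := p.adjust(p_raw, method = "bonferroni")]
  pw[, significant := p_bonf < alpha]
  list(omnibus_p = omnibus_p, video_means = colMeans(video_means), pairwise = pw)
}

#' Time course of the fraction of tuned units
#'
#' Per 150-ms bin (50-ms steps) and per unit, a one-way ANOVA across the
#' levels of the chosen factor on single-trial rates; the series is the
#' fraction of units with `P < alpha`. Each bin's fraction is compared with
#' the mean pre-onset (baseline) fraction by a chi-squared test on the 2x2
#' tuned/untuned x bin/baseline count table; the significance mask marks
#' bins whose fraction is significantly higher than baseline.
#'
#' @param rec a main-experiment `recording_set`.
#' @param factor_name `"exemplar"`, `"viewpoint"` or `"posture"`.
#' @param width,step bin width and step, s.
#' @param alpha per-unit and chi-squared significance level.
#' @param window analysis window (default baseline through video end).
#' @return data.table: `bin_start`, `fraction`, `chisq_p`, `significant`;
#'   attribute `baseline_fraction`.
#' @export
tuned_fraction_timecourse <- function(rec, factor_name = c("exemplar", "viewpoint", "posture"),
                                      width = 0.15, step = 0.05, alpha = 0.05,
                                      window = NULL) {
  factor_name <- match.arg(factor_name)
  window <- window %||% c(-rec$design$baseline_window, rec$design$video_duration)
  lev <- unique(rec$trials[[factor_name]])
  if (length(lev) < 2L) stop("factor has fewer than two levels")
  bt <- bin_rates(rec, width, step, window)
  f <- factor(rec$trials[[factor_name]])
  nu <- dim(bt$rates)[1]; nb <- dim(bt$rates)[3]
  pmat <- matrix(NA_real_, nu, nb)
  for (u in seq_len(nu)) for (b in seq_len(nb)) {
    y <- bt$rates[u, , b]
    if (sd(y) == 0) { pmat[u, b] <- 1; next }
    pmat[u, b] <- anova(lm(y ~ f))[["Pr(>F)"]][1]
  }
  tuned <- pmat < alpha
  frac <- colMeans(tuned)
  base_bins <- which(bt$bin_starts + width <= 0 + 1e-9)
  if (!length(base_bins)) stop("window contains no pre-onset baseline bins")
  base_frac <- mean(frac[base_bins])
  base_cnt <- round(base_frac * nu)
  chisq_p <- vapply(seq_len(nb), function(b) {
    tb <- matrix(c(sum(tuned[, b]), nu - sum(tuned[, b]),
                   base_cnt, nu - base_cnt), 2)
    if (any(rowSums(tb) == 0)) return(1)
    suppressWarnings(chisq.test(tb, correct = FALSE)$p.value)
  }, 0)
  out <- data.table(bin_start = bt$bin_starts, fraction = frac,
                    chisq_p = chisq_p,
                    significant = chisq_p < alpha & frac > base_frac)
  setattr(out, "baseline_fraction", base_frac)
  out
}
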