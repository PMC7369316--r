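## Across-format rank stability index (RSI).
##
## In sliding 500-ms bins (20-ms steps) the seven exemplars are ranked by
## trial-averaged rate within each format. In a reference format the
## preferred exemplar (rank 1) is identified; Rf_i is its rank in each of
## the n = 3 test formats, and
##     RSIr = 1 + sum_i (1 - (1/7)(Rf_i - 1)),
## ranging from 10/7 (preferred exemplar is worst everywhere) to 4
## (preferred everywhere). Normalizing by the achievable range maps RSI to
## [0, 1]; under independent uniform ranks the exact null mean is 0.5 and
## the support is 19 equally spaced values. Being rank-based, RSI is
## invariant to any monotone rescaling of firing rates within a format.

RSIR_MIN <- 1 + 3 * (1 - 6 / 7)   # 10/7
RSIR_MAX <- 4

#' Rank exemplars within each format
#'
#' Rank 1 = highest mean rate; ties break by the fixed (alphabetical)
#' exemplar order.
#'
#' @param means 4 x 7 matrix of trial-averaged rates (formats x
#'   exemplars).
#' @return 4 x 7 integer matrix of ranks (each row a permutation of 1..7).
#' @export
rank_exemplars <- function(means) {
  stopifnot(is.matrix(means), all(dim(means) == c(4, 7)), all(is.finite(means)))
  out <- t(apply(means, 1, function(x) {
    if (anyDuplicated(x)) message("tied exemplar means: tie broken by exemplar order")
    as.integer(rank(-x, ties.method = "first"))
  }))
  dimnames(out) <- dimnames(means)
  out
}

#' Raw rank stability index
#'
#' @param Rf integer vector of the 3 test-format ranks of the
#'   reference-format preferred exemplar, each in 1..7.
#' @return `RSIr = 1 + sum(1 - (Rf - 1)/7)`, in `[10/7, 4]`.
#' @export
rsi_raw <- function(Rf) {
  if (length(Rf) != 3L || any(Rf != round(Rf)) || any(Rf < 1) || any(Rf > 7))
    stop("Rf must be 3 integer ranks in 1..7")
  1 + sum(1 - (Rf - 1) / 7)
}

#' Normalize a raw RSI value to [0, 1]
#'
#' `rsi = (RSIr - 10/7) / (4 - 10/7)`.
#' @param RSIr raw value(s) in `[10/7, 4]`.
#' @return normalized value(s) in `[0, 1]`.
#' @export
rsi_normalize <- function(RSIr) {
  if (any(RSIr < RSIR_MIN - 1e-9 | RSIr > RSIR_MAX + 1e-9))
    stop("RSIr out of [10/7, 4]")
  (RSIr - RSIR_MIN) / (RSIR_MAX - RSIR_MIN)
}

#' Enumerate the exact RSI value set and null distribution
#'
#' All 7^3 = 343 equally likely rank triples under the unconstrained
#' shuffling null: the distinct normalized values (19, equally spaced on
#' [0, 1]) with their exact probabilities, and the exact null mean (0.5).
#'
#' @return list: `values` (data.table `rsi`, `probability`),
#'   `n_distinct`, `mean`.
#' @export
enumerate_rsi_values <- function() {
  g <- as.matrix(expand.grid(1:7, 1:7, 1:7))
  rsi <- rsi_normalize(apply(g, 1, rsi_raw))
  tab <- as.data.table(table(round(rsi, 10)))
  setnames(tab, c("rsi", "probability"))
  tab[, rsi := as.numeric(rsi)]
  tab[, probability := probability / nrow(g)]
  setorder(tab, rsi)
  list(values = tab, n_distinct = nrow(tab), mean = sum(tab$rsi * tab$probability))
}

#' Time-resolved RSI for one unit
#'
#' Computes, in sliding bins (default 500 ms / 20 ms) over the whole trial
#' period, the exemplar ranks per format from trial-averaged rates, the
#' test-format ranks `Rf` of the reference format's preferred exemplar,
#' and the raw and normalized RSI. The total score sums normalized RSI
#' over bins whose windows lie entirely within epochs 1+2 (`[0, 1.5)` s).
#'
#' @param rec a main-experiment `recording_set`.
#' @param unit_id unit to analyse.
#' @param reference_format reference format (default `"stand_lateral"`).
#' @param width,step bin width and step, s.
#' @param window analysis extent (default whole trial).
#' @param binned optional precomputed [bin_rates()] tensor (must match
#'   width/step/window); avoids rebinning when looping over units.
#' @return object of class `rsi_timecourse`: data.table (`bin_start`,
#'   `rsi_raw`, `rsi`), `Rf` (3 x bins matrix), `total_score`,
#'   `reference_format`.
#' @export
rsi_timecourse <- function(rec, unit_id, reference_format = "stand_lateral",
                           width = 0.5, step = 0.02, window = NULL,
                           binned = NULL) {
  stopifnot(reference_format %in% OMA_FORMATS)
  window <- window %||% c(-rec$design$baseline_window, rec$design$video_duration)
  bt <- binned %||% bin_rates(rec, width, step, window)
  u <- match(unit_id, bt$unit_ids)
  if (is.na(u)) stop("unknown unit id: ", unit_id)
  means_by_bin <- cell_mean_tensor_unit(bt, u)  # 4 x 7 x bins
  nb <- dim(means_by_bin)[3]
  test_formats <- setdiff(OMA_FORMATS, reference_format)
  Rf <- matrix(NA_integer_, 3, nb, dimnames = list(test_formats, NULL))
  rr <- numeric(nb)
  ref_i <- match(reference_format, OMA_FORMATS)
  ti <- match(test_formats, OMA_FORMATS)
  for (b in seq_len(nb)) {
    rk <- suppressMessages(rank_exemplars(means_by_bin[, , b]))
    best <- which(rk[ref_i, ] == 1L)
    Rf[, b] <- rk[ti, best]
    rr[b] <- rsi_raw(Rf[, b])
  }
  rsi <- rsi_normalize(rr)
  in_e12 <- bt$bin_starts >= -1e-9 & bt$bin_starts + width <= 1.5 + 1e-9
  structure(list(
    series = data.table(bin_start = bt$bin_starts, rsi_raw = rr, rsi = rsi),
    Rf = Rf, total_score = sum(rsi[in_e12]),
    epoch_bins = in_e12,
    reference_format = reference_format, unit_id = unit_id,
    bin_width_s = width, bin_step_s = step
  ), class = "rsi_timecourse")
}

## Trial-averaged 4 x 7 x bins cell-mean tensor for one unit is needed;
## compute it lazily from the binned tensor for a single unit index.
cell_mean_tensor_unit <- function(bt, u) {
  fi <- match(bt$trials$format, OMA_FORMATS)
  ei <- match(bt$trials$exemplar, OMA_EXEMPLARS)
  cell <- (ei - 1L) * 4L + fi
  G <- matrix(0, 28, nrow(bt$trials))
  G[cbind(cell, seq_len(nrow(bt$trials)))] <- 1
  G <- G / rowSums(G)
  r <- bt$rates[u, , ]                 # trials x bins
  m <- G %*% r                          # 28 x bins
  array(m, dim = c(4, 7, dim(bt$rates)[3]),
        dimnames = list(OMA_FORMATS, OMA_EXEMPLARS, NULL))
}

#' Shuffled nulls for an RSI timecourse
#'
#' Unconstrained: every `Rf_i` in every bin is replaced by an independent
#' uniform draw on 1..7 (chance distribution, mean 0.5). Constrained: per
#' test format one random mapping of rank values 1..7 to uniform draws on
#' 1..7 (collisions allowed) is applied to all bins, preserving the
#' temporal structure of rank changes; a bijective-permutation variant is
#' available via `bijective = TRUE`.
#'
#' @param tc an [rsi_timecourse()].
#' @param n_perms number of shuffles (>= 1).
#' @param seed seed.
#' @param constrained use the constrained (structure-preserving) null.
#' @param bijective constrained variant with a permutation mapping.
#' @return matrix `n_perms` x bins of null normalized RSI values.
#' @export
rsi_shuffle_null <- function(tc, n_perms, seed, constrained = FALSE,
                             bijective = FALSE) {
  stopifnot(inherits(tc, "rsi_timecourse"))
  if (n_perms < 1) stop("n_perms must be >= 1")
  nb <- ncol(tc$Rf)
  with_seed(seed, {
    out <- matrix(NA_real_, n_perms, nb)
    for (p in seq_len(n_perms)) {
      Rf_null <- if (constrained) {
        maps <- replicate(3, if (bijective) sample(7L) else
                               sample(7L, 7L, replace = TRUE))
        matrix(maps[cbind(as.vector(tc$Rf), rep(1:3, nb))], 3, nb)
      } else {
        matrix(sample(7L, 3L * nb, replace = TRUE), 3, nb)
      }
      out[p, ] <- rsi_normalize(
        1 + colSums(1 - (Rf_null - 1) / 7))
    }
    out
  })
}

#' RSI timecourses for a set of units
#'
#' @param rec a main-experiment `recording_set`.
#' @param unit_ids units (default all).
#' @inheritParams rsi_timecourse
#' @return named list of `rsi_timecourse` objects.
#' @export
rsi_population <- function(rec, unit_ids = NULL,
                           reference_format = "stand_lateral",
                           width = 0.5, step = 0.02, window = NULL) {
  ids <- unit_ids %||% rec$units$unit_id
  window <- window %||% c(-rec$design$baseline_window, rec$design$video_duration)
  bt <- bin_rates(rec, width, step, window)
  setNames(lapply(ids, function(u)
    rsi_timecourse(rec, u, reference_format, width, step, window, binned = bt)),
    ids)
}

#' Split a population into relatively stable / unstable halves
#'
#' Units are sorted by total RSI score (descending); the top
#' `floor(n / 2)` are labelled `stable`, the rest `unstable` (so 113 units
#' split 56 / 57).
#'
#' @param total_scores named numeric vector (names = unit ids) of total
#'   RSI scores.
#' @return data.table: `unit_id`, `total_score`, `stability_label`.
#' @export
stability_split <- function(total_scores) {
  if (length(total_scores) < 2) stop("need at least 2 units")
  ord <- order(total_scores, decreasing = TRUE)
  n_stable <- floor(length(total_scores) / 2)
  lab <- character(length(total_scores))
  lab[ord[seq_len(n_stable)]] <- "stable"
  lab[ord[-seq_len(n_stable)]] <- "unstable"
  data.table(unit_id = names(total_scores) %||% as.character(seq_along(total_scores)),
             total_score = as.numeric(total_scores),
             stability_label = lab)
}

#' Compare real and null RSI score distributions
#'
#' Two-sample t-test of the real per-unit scores against null scores (the
#' statistic form used for the real-vs-chance and real-vs-constrained
#' contrasts).
#'
#' @param real,null numeric vectors of scores.
#' @return list: `t`, `df`, `p`, `mean_real`, `mean_null`.
#' @export
rsi_vs_null_test <- function(real, null) {
  tt <- t.test(real, null)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       mean_real = mean(real), mean_null = mean(null))
}

#' RSI summaries under each choice of reference format
#'
#' @param rec a main-experiment `recording_set`.
#' @param unit_ids units (default all).
#' @param width,step RSI binning.
#' @return data.table: `reference_format`, `mean_rsi` (over units and
#'   epoch-1+2 bins), `mean_total_score`.
#' @export
reference_robustness <- function(rec, unit_ids = NULL, width = 0.5, step = 0.02) {
  if (length(unique(rec$trials$format)) < 4)
    stop("all four formats are required")
  rows <- lapply(OMA_FORMATS, function(ref) {
    tcs <- rsi_population(rec, unit_ids, reference_format = ref,
                          width = width, step = step)
    mr <- mean(vapply(tcs, function(tc) mean(tc$series$rsi[tc$epoch_bins]), 0))
    ts <- mean(vapply(tcs, `[[`, 0, "total_score"))
    data.table(reference_format = ref, mean_rsi = mr, mean_total_score = ts)
  })
  rbindlist(rows)
}
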