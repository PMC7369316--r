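## Additive vs. multiplicative integration of format and OMA identity.
##
## Per unit, the object of study is the 4 (format) x 7 (exemplar) response
## matrix of mean rates. Models are fitted on one half of the trials (the
## training matrix O') and correlated with the held-out half (O):
##   additive:        A_ij = k1 E_i + k2 F_j, E = column (exemplar) means,
##                    F = row (format) means, (k1, k2) by least squares;
##   multiplicative:  M = s1 u1 v1', the leading rank-1 SVD reconstruction
##                    of O' (the best rank-1 approximation in Frobenius
##                    norm, by Eckart-Young);
##   observed:        O' itself (split-half reliability, the noise ceiling).
## Comparison statistic: squared Pearson correlation over the 28 entries.

#' Split a unit's trials into two half response matrices
#'
#' @param trial_rates data.table for one unit: `trial_id`, `exemplar`,
#'   `format`, `rate`.
#' @param mode `"even_odd"` (by trial-number parity, the presentation
#'   order) or `"random"` (each cell split as evenly as possible at
#'   random).
#' @param seed required for `mode = "random"`.
#' @return list of two 4 x 7 matrices `O` (first half: even trials) and
#'   `Oprime` (second half: odd trials / random complement).
#' @export
split_half_matrices <- function(trial_rates, mode = c("even_odd", "random"),
                                seed = NULL) {
  mode <- match.arg(mode)
  d <- as.data.table(trial_rates)
  stopifnot(all(c("trial_id", "exemplar", "format", "rate") %in% names(d)))
  if (mode == "even_odd") {
    d[, half := ifelse(trial_id %% 2L == 0L, "A", "B")]
  } else {
    if (is.null(seed)) stop("random mode requires a seed")
    d[, half := with_seed(seed, {
      h <- character(nrow(d))
      for (cell in split(seq_len(nrow(d)),
                         paste(d$format, d$exemplar))) {
        na <- floor(length(cell) / 2)
        pick <- sample(cell, na)
        h[pick] <- "A"; h[setdiff(cell, pick)] <- "B"
      }
      h
    })]
  }
  cnt <- d[, .N, by = .(format, exemplar, half)]
  full <- CJ(format = OMA_FORMATS, exemplar = OMA_EXEMPLARS, half = c("A", "B"))
  if (nrow(cnt) < nrow(full))
    stop("empty exemplar x format cell in one half of the trials")
  mk <- function(h) {
    m <- matrix(NA_real_, 4, 7, dimnames = list(OMA_FORMATS, OMA_EXEMPLARS))
    agg <- d[half == h, .(rate = mean(rate)), by = .(format, exemplar)]
    m[cbind(agg$format, agg$exemplar)] <- agg$rate
    m
  }
  list(O = mk("A"), Oprime = mk("B"))
}

#' Fit the additive format + exemplar model
#'
#' `E` = exemplar activations (column means of the training matrix), `F` =
#' format activations (row means); the two constants minimize
#' `sum((T_ij - c - k1 E_i - k2 F_j)^2)` over the 28 entries by ordinary
#' least squares. The prediction is `A_ij = k1 E_i + k2 F_j`; the nuisance
#' offset `c` is estimated (it absorbs the shared baseline in `E` and `F`,
#' which would otherwise bias `k1`, `k2` away from each other) but not
#' added to `A` — the comparison statistic, a Pearson correlation, is
#' translation-invariant so the offset is irrelevant downstream.
#'
#' @param train 4 x 7 training response matrix.
#' @return list: `E` (7), `F` (4), `k1`, `k2`, `A` (4 x 7 prediction).
#' @export
fit_additive <- function(train) {
  stopifnot(is.matrix(train), all(dim(train) == c(4, 7)), all(is.finite(train)))
  E <- colMeans(train); Fv <- rowMeans(train)
  X <- cbind(1, E_i = rep(E, each = 4), F_j = rep(Fv, times = 7))
  y <- as.vector(train)
  if (qr(X)$rank < 3L) {
    message("degenerate additive design (constant E and F): k1 = k2 = 0.5")
    k <- c(0, 0.5, 0.5)
  } else {
    k <- lm.fit(X, y)$coefficients
  }
  A <- k[2] * matrix(E, 4, 7, byrow = TRUE) + k[3] * matrix(Fv, 4, 7)
  dimnames(A) <- dimnames(train)
  list(E = E, F = Fv, k1 = unname(k[2]), k2 = unname(k[3]), A = A)
}

#' Fit the multiplicative (rank-1 SVD) model
#'
#' `M = s1 u1 v1'`, the leading singular triplet of the training matrix:
#' the closest rank-1 matrix in Frobenius norm. The product is unique
#' whenever `s1 > s2` (the sign ambiguity of `u1`, `v1` cancels).
#'
#' @param train 4 x 7 training response matrix.
#' @return list: `u1` (4), `s1`, `v1` (7), `M` (4 x 7 prediction).
#' @export
fit_multiplicative <- function(train) {
  stopifnot(is.matrix(train), all(dim(train) == c(4, 7)), all(is.finite(train)))
  if (all(train == 0)) {
    message("all-zero training matrix: multiplicative prediction is 0")
    M <- train
    return(list(u1 = rep(0, 4), s1 = 0, v1 = rep(0, 7), M = M))
  }
  sv <- svd(train)
  if (length(sv$d) > 1 && abs(sv$d[1] - sv$d[2]) < 1e-12 * max(sv$d))
    message("tied leading singular values: rank-1 factor not unique")
  M <- sv$d[1] * tcrossprod(sv$u[, 1], sv$v[, 1])
  dimnames(M) <- dimnames(train)
  list(u1 = sv$u[, 1], s1 = sv$d[1], v1 = sv$v[, 1], M = M)
}

#' Squared Pearson correlation between prediction and held-out matrix
#'
#' @param prediction,heldout matrices of matching shape.
#' @return squared Pearson correlation over the vectorized entries, or
#'   `NA` when the held-out matrix is constant (undefined; the unit is
#'   dropped from population statistics).
#' @export
model_r2 <- function(prediction, heldout) {
  stopifnot(all(dim(prediction) == dim(heldout)))
  if (sd(as.vector(heldout)) == 0 || sd(as.vector(prediction)) == 0) {
    message("constant matrix: split-half correlation undefined (NA)")
    return(NA_real_)
  }
  cor(as.vector(prediction), as.vector(heldout))^2
}

#' Cross-validated mixing-model fit for one unit
#'
#' Splits trials in half, fits the additive and multiplicative models on
#' the training half `O'` and correlates the predictions (and `O'` itself,
#' the observed split-half reliability) with the held-out matrix `O`.
#'
#' @inheritParams split_half_matrices
#' @param constants_on fit the additive constants on the `"train"` half
#'   (default, self-contained cross-validation) or on the `"test"` half.
#' @return one-row data.table: `r2_observed`, `r2_multiplicative`,
#'   `r2_additive`, `k1`, `k2`, `s1`.
#' @export
fit_mixing_unit <- function(trial_rates, mode = "even_odd", seed = NULL,
                            constants_on = c("train", "test")) {
  constants_on <- match.arg(constants_on)
  sh <- split_half_matrices(trial_rates, mode, seed)
  O <- sh$O; Op <- sh$Oprime
  add <- fit_additive(Op)
  if (constants_on == "test") {
    X <- cbind(1, rep(add$E, each = 4), rep(add$F, times = 7))
    if (qr(X)$rank == 3L) {
      k <- lm.fit(X, as.vector(O))$coefficients
      add$k1 <- unname(k[2]); add$k2 <- unname(k[3])
      add$A <- add$k1 * matrix(add$E, 4, 7, byrow = TRUE) +
               add$k2 * matrix(add$F, 4, 7)
    }
  }
  mult <- fit_multiplicative(Op)
  data.table(
    r2_observed = model_r2(Op, O),
    r2_multiplicative = model_r2(mult$M, O),
    r2_additive = model_r2(add$A, O),
    k1 = add$k1, k2 = add$k2, s1 = mult$s1
  )
}

#' Epoch-2 mixing fits for every unit of a recording set
#'
#' @param rec a main-experiment `recording_set`.
#' @param window response window (default epoch 2).
#' @inheritParams fit_mixing_unit
#' @param seed master seed (random mode: one substream per unit).
#' @return data.table with one row per unit.
#' @export
fit_mixing_population <- function(rec, window = epoch_windows()$epoch2,
                                  mode = "even_odd", seed = NULL,
                                  constants_on = "train") {
  er <- epoch_rates(rec, list(win = window))
  er <- merge(er, rec$trials[, .(trial_id, exemplar, format)], by = "trial_id")
  setkey(er, unit_id)
  rows <- lapply(seq_len(nrow(rec$units)), function(k) {
    u <- rec$units$unit_id[k]
    fit <- fit_mixing_unit(er[.(u)], mode = mode,
                           seed = if (is.null(seed)) NULL else substream_seed(seed, k),
                           constants_on = constants_on)
    cbind(data.table(unit_id = u), fit)
  })
  rbindlist(rows)
}

#' Mann-Whitney U test (normal approximation with tie correction)
#'
#' Reports the U statistic and the tie-corrected Z of the normal
#' approximation; for small samples (either group < 8) the exact p-value
#' is used instead of the approximation.
#'
#' @param x,y numeric samples.
#' @return list: `U`, `Z`, `p`.
#' @export
mann_whitney <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(c(x, y))
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  sigma <- sqrt(n1 * n2 / 12 * ((N + 1) - tie_term))
  Z <- if (sigma > 0) (U - mu) / sigma else 0
  p <- if (min(n1, n2) < 8) {
    suppressWarnings(wilcox.test(x, y, exact = TRUE)$p.value)
  } else 2 * pnorm(-abs(Z))
  list(U = U, Z = Z, p = p)
}

#' Population comparison of the three model R2 distributions
#'
#' @param fits data.table from [fit_mixing_population()].
#' @return list: `medians` (observed / multiplicative / additive) and
#'   `tests` (pairwise Mann-Whitney U, Z, p).
#' @export
compare_models_population <- function(fits) {
  stopifnot(nrow(fits) >= 2)
  cols <- c("r2_observed", "r2_multiplicative", "r2_additive")
  meds <- vapply(cols, function(cl) median(fits[[cl]], na.rm = TRUE), 0)
  prs <- combn(cols, 2, simplify = FALSE)
  tests <- rbindlist(lapply(prs, function(pr) {
    mw <- mann_whitney(fits[[pr[1]]], fits[[pr[2]]])
    data.table(a = pr[1], b = pr[2], U = mw$U, Z = mw$Z, p = mw$p)
  }))
  list(medians = meds, tests = tests)
}

## Runs-of-significant-bins mask: keep only runs of >= min_run TRUEs.
mask_runs <- function(sig, min_run = 4L) {
  sig[is.na(sig)] <- FALSE
  r <- rle(sig)
  r$values <- r$values & r$lengths >= min_run
  inverse.rle(r)
}

#' Time-resolved additive / multiplicative / observed comparison
#'
#' In sliding windows (150 ms / 50 ms), each unit's trials are split at
#' random within each exemplar x format cell, models are fitted on one half
#' and correlated with the other; per-unit values are averaged over
#' `n_repeats` random splits. Population curves are unit means; pairwise
#' differences are tested per window with a sliding Wilcoxon signed-rank
#' test across units, and only runs of at least `min_run` consecutive
#' significant windows are retained in the masks.
#'
#' @param rec a main-experiment `recording_set`.
#' @param unit_ids units to include (default all).
#' @param width,step window width and step, s.
#' @param n_repeats random split repeats per window (default 20).
#' @param seed master seed.
#' @param window analysis extent (default video period).
#' @param alpha per-window significance level.
#' @param min_run minimum run length of significant windows.
#' @return list: `bin_starts`, `mean_r2` (data.table of the three
#'   population curves), `p` (pairwise p-value series), `masks` (logical
#'   series per pair), `per_unit` (unit x window x model array).
#' @export
time_resolved_comparison <- function(rec, unit_ids = NULL, width = 0.15,
                                     step = 0.05, n_repeats = 20, seed,
                                     window = NULL, alpha = 0.05,
                                     min_run = 4L) {
  if (missing(seed)) stop("a seed is required")
  window <- window %||% c(0, rec$design$video_duration)
  ids <- unit_ids %||% rec$units$unit_id
  ki <- match(ids, rec$units$unit_id)
  bt <- bin_rates(rec, width, step, window)
  nb <- length(bt$bin_starts)
  cell <- paste(rec$trials$format, rec$trials$exemplar)
  cell_idx <- split(seq_len(nrow(rec$trials)), cell)
  fi <- match(rec$trials$format, OMA_FORMATS)
  ei <- match(rec$trials$exemplar, OMA_EXEMPLARS)

  per_unit <- array(NA_real_, dim = c(length(ids), nb, 3),
                    dimnames = list(ids, NULL, c("observed", "multiplicative", "additive")))
  for (b in seq_len(nb)) {
    acc <- matrix(0, length(ids), 3)
    nok <- matrix(0, length(ids), 3)
    for (r in seq_len(n_repeats)) {
      halfA <- with_seed(substream_seed(seed, b, r), {
        h <- logical(nrow(rec$trials))
        for (cidx in cell_idx) h[sample(cidx, floor(length(cidx) / 2))] <- TRUE
        h
      })
      for (q in seq_along(ids)) {
        y <- bt$rates[ki[q], , b]
        O  <- tapply_mean_47(y[halfA], fi[halfA], ei[halfA])
        Op <- tapply_mean_47(y[!halfA], fi[!halfA], ei[!halfA])
        if (anyNA(O) || anyNA(Op)) next
        add <- fit_additive(Op)
        mult <- fit_multiplicative(Op)
        vals <- c(suppressMessages(model_r2(Op, O)),
                  suppressMessages(model_r2(mult$M, O)),
                  suppressMessages(model_r2(add$A, O)))
        ok <- is.finite(vals)
        acc[q, ok] <- acc[q, ok] + vals[ok]
        nok[q, ok] <- nok[q, ok] + 1
      }
    }
    per_unit[, b, ] <- acc / pmax(nok, 1)
    per_unit[, b, ][nok == 0] <- NA_real_
  }

  mean_r2 <- data.table(
    bin_start = bt$bin_starts,
    observed = colMeans(per_unit[, , 1, drop = FALSE], na.rm = TRUE)[, 1],
    multiplicative = colMeans(per_unit[, , 2, drop = FALSE], na.rm = TRUE)[, 1],
    additive = colMeans(per_unit[, , 3, drop = FALSE], na.rm = TRUE)[, 1])

  pairs <- list(c("multiplicative", "additive"),
                c("observed", "multiplicative"),
                c("observed", "additive"))
  p <- list(); masks <- list()
  for (pr in pairs) {
    nm <- paste(pr, collapse = "_vs_")
    pv <- vapply(seq_len(nb), function(b) {
      a <- per_unit[, b, pr[1]]; bb <- per_unit[, b, pr[2]]
      ok <- is.finite(a) & is.finite(bb)
      if (sum(ok) < 3 || all(a[ok] == bb[ok])) return(1)
      suppressWarnings(wilcox.test(a[ok], bb[ok], paired = TRUE)$p.value)
    }, 0)
    p[[nm]] <- pv
    masks[[nm]] <- mask_runs(pv < alpha, min_run)
  }
  list(bin_starts = bt$bin_starts, mean_r2 = mean_r2, p = p, masks = masks,
       per_unit = per_unit)
}

## Mean 4 x 7 matrix of y by (format index, exemplar index); NA for empty cells.
tapply_mean_47 <- function(y, fi, ei) {
  s <- matrix(0, 4, 7); n <- matrix(0L, 4, 7)
  idx <- cbind(fi, ei)
  for (i in seq_along(y)) {
    s[idx[i, 1], idx[i, 2]] <- s[idx[i, 1], idx[i, 2]] + y[i]
    n[idx[i, 1], idx[i, 2]] <- n[idx[i, 1], idx[i, 2]] + 1L
  }
  out <- s / n
  out[n == 0L] <- NA_real_
  out
}
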