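## Pseudopopulation decoding with a Poisson naive Bayes (PNB) classifier.
##
## Units recorded separately are treated as if simultaneous: per unit,
## trials of each condition are randomly distributed across splits; a
## "data point" is the concatenation of one trial per unit within a split.
## The split structure follows the factorial design: conditions are the 7
## exemplars, optionally crossed with the decoded format factor
## (viewpoint/posture), giving 48 x 7 = 336 data points for
## format-independent OMA decoding, 24 x 7 = 168 for viewpoint or posture
## decoding and 12 x 7 = 84 for single-format OMA (cross-)decoding.
## Classification uses leave-one-split-out cross-validation on raw spike
## counts; the full train-time x test-time generalization matrix is
## computed in 150-ms bins stepped by 50 ms.

#' Assemble a pseudopopulation from binned counts
#'
#' @param binned a [bin_rates()] result (its `counts` and `trials` are
#'   used).
#' @param factor_name decoded factor: `"exemplar"`, `"viewpoint"` or
#'   `"posture"`.
#' @param format restrict to a single format (for single-format OMA
#'   decoding / cross-decoding), or `NULL`.
#' @param seed split-assignment seed.
#' @param shuffle_labels permute, per unit, the assignment of trials to
#'   conditions before building splits (used by the permutation null).
#' @return object of class `pseudopopulation`: `X` (unit x cell x split x
#'   bin count array), `cells` (cell table with exemplar and class label),
#'   `classes` (factor levels), `n_splits`, `n_data_points`
#'   (= n_splits x 7), `bin_starts`.
#' @export
build_pseudopopulation <- function(binned, factor_name = c("exemplar", "viewpoint", "posture"),
                                   format = NULL, seed, shuffle_labels = FALSE) {
  factor_name <- match.arg(factor_name)
  if (missing(seed)) stop("a seed is required")
  trials <- copy(binned$trials)
  keep <- rep(TRUE, nrow(trials))
  if (!is.null(format)) {
    stopifnot(format %in% OMA_FORMATS)
    keep <- trials$format == format
  }
  trials <- trials[keep]
  cnt <- binned$counts[, keep, , drop = FALSE]

  cells <- if (factor_name == "exemplar") {
    data.table(exemplar = OMA_EXEMPLARS, class = OMA_EXEMPLARS)
  } else {
    CJ(exemplar = OMA_EXEMPLARS, class = unique(trials[[factor_name]]))
  }
  cells[, cell_id := .I]
  cell_of_trial <- if (factor_name == "exemplar") {
    match(trials$exemplar, OMA_EXEMPLARS)
  } else {
    cells[trials[, .(exemplar = exemplar, class = get(factor_name))],
          on = c("exemplar", "class"), cell_id]
  }
  sizes <- tabulate(cell_of_trial, nbins = nrow(cells))
  if (any(sizes == 0))
    stop("condition with zero trials: ",
         paste(cells$exemplar[sizes == 0], cells$class[sizes == 0], collapse = ", "))
  n_splits <- min(sizes)
  if (n_splits < 2)
    stop("fewer than 2 trials per condition (",
         cells$exemplar[which.min(sizes)], "): cannot build splits")

  nu <- dim(cnt)[1]; nb <- dim(cnt)[3]
  nc <- nrow(cells)
  X <- array(0, dim = c(nu, nc, n_splits, nb))
  cell_trials <- split(seq_len(nrow(trials)), cell_of_trial)
  with_seed(seed, {
    for (u in seq_len(nu)) {
      tr_idx <- if (shuffle_labels) sample(seq_len(nrow(trials))) else seq_len(nrow(trials))
      for (ci in seq_len(nc)) {
        pool <- tr_idx[cell_trials[[as.character(ci)]]]
        pick <- sample(pool, n_splits)
        X[u, ci, , ] <- cnt[u, pick, ]
      }
    }
  })
  structure(list(X = X, cells = cells, classes = unique(cells$class),
                 n_splits = n_splits,
                 n_data_points = n_splits * length(OMA_EXEMPLARS),
                 bin_starts = binned$bin_starts,
                 unit_ids = binned$unit_ids,
                 factor_name = factor_name, format = format),
            class = "pseudopopulation")
}

#' @export
print.pseudopopulation <- function(x, ...) {
  cat(sprintf("<pseudopopulation: %d units, %d x %d = %d data points, factor %s>\n",
              dim(x$X)[1], x$n_splits, length(OMA_EXEMPLARS),
              x$n_data_points, x$factor_name))
  invisible(x)
}

#' Train a Poisson naive Bayes classifier
#'
#' Per unit and class, the rate parameter is the mean training count,
#' floored at `eps` (default `1 / (2 x number of training points)`) so
#' log-likelihoods stay finite.
#'
#' @param counts units x data-points matrix of nonnegative counts.
#' @param classes class label per data point.
#' @param eps lambda floor.
#' @return object of class `pnb_model`: `lambda` (units x classes),
#'   `classes`.
#' @export
pnb_train <- function(counts, classes, eps = NULL) {
  if (any(counts < 0)) stop("negative counts: PNB requires raw nonnegative counts")
  classes <- as.character(classes)
  lev <- unique(classes)
  eps <- eps %||% (1 / (2 * ncol(counts)))
  lambda <- vapply(lev, function(cl)
    rowMeans(counts[, classes == cl, drop = FALSE]), numeric(nrow(counts)))
  lambda <- pmax(matrix(lambda, nrow(counts), length(lev),
                        dimnames = list(NULL, lev)), eps)
  structure(list(lambda = lambda, classes = lev), class = "pnb_model")
}

#' Predict classes with a Poisson naive Bayes model
#'
#' The predicted class maximizes `sum_u (n_u log lambda_uc - lambda_uc)`
#' (the constant `log n_u!` is dropped); ties break deterministically to
#' the lowest class index.
#'
#' @param model a [pnb_train()] model.
#' @param counts units x data-points matrix.
#' @return character vector of predicted classes.
#' @export
pnb_predict <- function(model, counts) {
  model$classes[max.col(pnb_scores(model, counts), ties.method = "first")]
}

#' @rdname pnb_predict
#' @return `pnb_scores`: data-points x classes log-likelihood matrix.
#' @export
pnb_scores <- function(model, counts) {
  if (any(counts < 0)) stop("negative counts: PNB requires raw nonnegative counts")
  sc <- crossprod(counts, log(model$lambda))
  sweep(sc, 2, colSums(model$lambda))
}

## Correlation-based alternative classifier: z-score each unit with
## training-split parameters, correlate with class mean templates.
cor_train <- function(counts, classes) {
  mu <- rowMeans(counts); s <- apply(counts, 1, sd); s[s == 0] <- 1
  z <- (counts - mu) / s
  lev <- unique(as.character(classes))
  templ <- vapply(lev, function(cl)
    rowMeans(z[, classes == cl, drop = FALSE]), numeric(nrow(counts)))
  list(mu = mu, s = s, templates = matrix(templ, ncol = length(lev),
                                          dimnames = list(NULL, lev)),
       classes = lev)
}

cor_predict_scores <- function(model, counts) {
  z <- (counts - model$mu) / model$s
  suppressWarnings(cor(z, model$templates))
}

## lambda (or templates) per bin for one training fold.
## X: unit x cell x split x bin. Returns list per bin of trained model.
fold_models <- function(X, cell_class, test_split, method, eps) {
  nu <- dim(X)[1]; nb <- dim(X)[4]
  tr <- setdiff(seq_len(dim(X)[3]), test_split)
  lapply(seq_len(nb), function(b) {
    M <- X[, , tr, b, drop = FALSE]
    dim(M) <- c(nu, length(cell_class) * length(tr))
    cls <- rep(cell_class, times = length(tr))
    if (method == "pnb") pnb_train(M, cls, eps) else cor_train(M, cls)
  })
}

#' Decode a factor from pseudopopulation activity
#'
#' Leave-one-split-out cross-validated decoding, repeated over
#' `n_runs` random split assemblies and averaged; returns the full
#' train-bin x test-bin temporal-generalization accuracy matrix and its
#' diagonal. Bin timestamps refer to the bin start.
#'
#' @param binned a [bin_rates()] result (counts in 150/50-ms bins for the
#'   standard analysis).
#' @param factor_name decoded factor.
#' @param format optional single-format restriction.
#' @param n_runs resample runs (default 50).
#' @param seed master seed; each run uses an independent substream.
#' @param method `"pnb"` (default) or `"correlation"` (z-scored template
#'   correlation; z-score parameters from training splits only).
#' @param diagonal_only skip off-diagonal generalization (faster).
#' @param shuffle_labels build label-shuffled pseudopopulations (null).
#' @return object of class `accuracy_matrix`: `accuracy` (train x test
#'   bins), `diagonal`, `bin_starts`, `chance`, metadata.
#' @export
decode_factor <- function(binned, factor_name = "exemplar", format = NULL,
                          n_runs = 50, seed, method = c("pnb", "correlation"),
                          diagonal_only = FALSE, shuffle_labels = FALSE) {
  method <- match.arg(method)
  if (missing(seed)) stop("a seed is required")
  nb <- length(binned$bin_starts)
  acc <- matrix(0, nb, nb)
  n_classes <- NULL
  for (r in seq_len(n_runs)) {
    pp <- build_pseudopopulation(binned, factor_name, format,
                                 seed = substream_seed(seed, r, 11L),
                                 shuffle_labels = shuffle_labels)
    cls <- pp$cells$class
    n_classes <- length(pp$classes)
    truth <- as.character(cls)
    nu <- dim(pp$X)[1]; ncell <- length(cls)
    eps <- 1 / (2 * ncell * (pp$n_splits - 1))
    for (s in seq_len(pp$n_splits)) {
      models <- fold_models(pp$X, cls, s, method, eps)
      Te <- pp$X[, , s, , drop = FALSE]      # unit x cell x 1 x bin
      dim(Te) <- c(nu, ncell, nb)
      if (diagonal_only) {
        for (b in seq_len(nb)) {
          sc <- if (method == "pnb") pnb_scores(models[[b]], Te[, , b, drop = TRUE])
                else cor_predict_scores(models[[b]], matrix(Te[, , b], nu))
          pred <- models[[b]]$classes[max.col(sc, ties.method = "first")]
          acc[b, b] <- acc[b, b] + mean(pred == truth)
        }
      } else {
        Tall <- matrix(Te, nu, ncell * nb)    # cells vary fastest
        for (tb in seq_len(nb)) {
          sc <- if (method == "pnb") pnb_scores(models[[tb]], Tall)
                else cor_predict_scores(models[[tb]], Tall)
          pred <- models[[tb]]$classes[max.col(sc, ties.method = "first")]
          ok <- matrix(pred == rep(truth, times = nb), ncell, nb)
          acc[tb, ] <- acc[tb, ] + colMeans(ok)
        }
      }
    }
    acc_norm <- pp$n_splits
  }
  acc <- acc / (n_runs * acc_norm)
  structure(list(accuracy = acc, diagonal = diag(acc),
                 bin_starts = binned$bin_starts,
                 chance = 1 / n_classes, n_classes = n_classes,
                 factor_name = factor_name, format = format,
                 n_runs = n_runs, method = method,
                 shuffled = shuffle_labels),
            class = "accuracy_matrix")
}

#' @export
print.accuracy_matrix <- function(x, ...) {
  cat(sprintf("<accuracy_matrix: %d bins, factor %s, peak diagonal %.3f (chance %.3f)>\n",
              length(x$bin_starts), x$factor_name, max(x$diagonal), x$chance))
  invisible(x)
}

#' Permutation null and significance mask for a decoding time course
#'
#' The decoding analysis is rerun `n_shuffles` times with, per unit, the
#' condition labels randomly shuffled before pseudopopulation assembly.
#' A bin is significant when the real diagonal accuracy exceeds every
#' shuffled accuracy, and only runs of at least `min_run` consecutive
#' significant bins are retained; the onset is the start time of the first
#' significant bin.
#'
#' @param binned,factor_name,format,seed,method as [decode_factor()].
#' @param real an `accuracy_matrix` from [decode_factor()] on the real
#'   labels.
#' @param n_shuffles number of label shuffles (default 50).
#' @param n_runs_per_shuffle resample runs per shuffle (default 1).
#' @param min_run minimum significant run length (default 4).
#' @return list: `null` (shuffles x bins diagonal accuracies), `mask`,
#'   `onset_s` (NA when nothing is significant).
#' @export
permutation_null <- function(binned, real, factor_name = "exemplar",
                             format = NULL, n_shuffles = 50, seed,
                             n_runs_per_shuffle = 1, method = "pnb",
                             min_run = 4L) {
  if (missing(seed)) stop("a seed is required")
  if (n_shuffles < 1) stop("n_shuffles must be >= 1")
  stopifnot(inherits(real, "accuracy_matrix"))
  nb <- length(binned$bin_starts)
  nulls <- matrix(NA_real_, n_shuffles, nb)
  for (k in seq_len(n_shuffles)) {
    nd <- decode_factor(binned, factor_name, format,
                        n_runs = n_runs_per_shuffle,
                        seed = substream_seed(seed, k, 23L),
                        method = method, diagonal_only = TRUE,
                        shuffle_labels = TRUE)
    nulls[k, ] <- nd$diagonal
  }
  exceeds <- real$diagonal > apply(nulls, 2, max)
  mask <- mask_runs(exceeds, min_run)
  onset <- if (any(mask)) binned$bin_starts[which(mask)[1]] else NA_real_
  list(null = nulls, mask = mask, onset_s = onset)
}

#' Cross-format OMA decoding
#'
#' Trains the classifier on all splits of one format's pseudopopulation
#' and tests on another format's data points (84 = 12 x 7 per format).
#' When the two formats coincide the analysis is redirected to the
#' within-format leave-one-split-out decoding.
#'
#' @param binned a [bin_rates()] result.
#' @param train_format,test_format format labels.
#' @param n_runs resample runs.
#' @param seed master seed.
#' @param method classifier.
#' @return an `accuracy_matrix` (train x test bins).
#' @export
cross_format_decode <- function(binned, train_format, test_format,
                                n_runs = 50, seed, method = c("pnb", "correlation")) {
  method <- match.arg(method)
  if (missing(seed)) stop("a seed is required")
  stopifnot(train_format %in% OMA_FORMATS, test_format %in% OMA_FORMATS)
  if (identical(train_format, test_format)) {
    message("train and test formats coincide: within-format cross-validated decoding")
    return(decode_factor(binned, "exemplar", format = train_format,
                         n_runs = n_runs, seed = seed, method = method))
  }
  nb <- length(binned$bin_starts)
  acc <- matrix(0, nb, nb)
  for (r in seq_len(n_runs)) {
    ptr <- build_pseudopopulation(binned, "exemplar", train_format,
                                  seed = substream_seed(seed, r, 31L))
    pte <- build_pseudopopulation(binned, "exemplar", test_format,
                                  seed = substream_seed(seed, r, 37L))
    nu <- dim(ptr$X)[1]; ncell <- nrow(ptr$cells)
    truth <- rep(as.character(pte$cells$class), times = pte$n_splits)
    eps <- 1 / (2 * ncell * ptr$n_splits)
    for (tb in seq_len(nb)) {
      Mtr <- ptr$X[, , , tb, drop = FALSE]
      dim(Mtr) <- c(nu, ncell * ptr$n_splits)
      cls <- rep(ptr$cells$class, times = ptr$n_splits)
      model <- if (method == "pnb") pnb_train(Mtr, cls, eps) else cor_train(Mtr, cls)
      Mte <- aperm(pte$X[, , , , drop = FALSE], c(1, 2, 3, 4))
      Mte <- matrix(Mte, nu, ncell * pte$n_splits * nb)
      sc <- if (method == "pnb") pnb_scores(model, Mte) else cor_predict_scores(model, Mte)
      pred <- model$classes[max.col(sc, ties.method = "first")]
      ok <- matrix(pred == rep(truth, times = nb), ncell * pte$n_splits, nb)
      acc[tb, ] <- acc[tb, ] + colMeans(ok)
    }
  }
  acc <- acc / n_runs
  structure(list(accuracy = acc, diagonal = diag(acc),
                 bin_starts = binned$bin_starts, chance = 1 / 7,
                 n_classes = 7L, factor_name = "exemplar",
                 format = c(train = train_format, test = test_format),
                 n_runs = n_runs, method = method, shuffled = FALSE),
            class = "accuracy_matrix")
}
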