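## Internal helpers: seed substreams and argument validation.

#' Derive a reproducible substream seed from a master seed
#'
#' Mixes a master seed with one or more integer indices through a fixed
#' multiplicative hash so that independent parts of a simulation (units,
#' resample runs, shuffles) get decorrelated but fully reproducible streams.
#' The result is always a valid 32-bit R seed.
#'
#' @param seed master seed (single integer).
#' @param ... integer indices identifying the substream (unit index, run
#'   index, ...).
#' @return a single integer in `[0, 2^31 - 2]`.
#' @export
substream_seed <- function(seed, ...) {
  idx <- c(...)
  stopifnot(length(seed) == 1L, is.finite(seed))
  m <- 2147483647 # 2^31 - 1, prime
  h <- as.numeric(seed) %% m
  for (k in seq_along(idx)) {
    ## Knuth-style multiplicative mixing, kept exact in doubles (< 2^53)
    h <- (h * 48271 + (as.numeric(idx[k]) + 1) * 16807 + k * 377) %% m
    h <- (h * 69621) %% m
  }
  as.integer(h)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_scalar_number <- function(x, name, positive = FALSE) {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  invisible(x)
}
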