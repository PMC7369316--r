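## Neural state-space clustering of condition means.
##
## The population response to each condition is a cloud of time-point
## vectors in the N-dimensional unit space; conditions are compared by the
## Mahalanobis distance between cloud centroids under the pooled
## within-condition covariance, normalized by N (the distance grows
## linearly with population size), and clustered by average linkage
## (UPGMA) with optimal leaf ordering of the dendrogram.

#' Build a units x (conditions x time points) firing matrix
#'
#' Trial-averaged rates in sliding bins within the epoch of interest,
#' grouped by condition: exemplars pooled over formats
#' (`"format_independent"`, 7 conditions) or exemplar x format
#' (`"format_dependent"`, 28 conditions).
#'
#' @param rec a main-experiment `recording_set`.
#' @param mode condition definition.
#' @param window epoch of interest (default epochs 1+2, `[0, 1.5)` s).
#' @param width,step binning of the trial-averaged rates (default
#'   60 ms / 20 ms).
#' @return object of class `state_space_matrix`: `F` (N x c*t), `condition`
#'   and `bin_start` labels per column, `n_units`, `n_conditions`,
#'   `n_timepoints`.
#' @export
state_space_matrix <- function(rec, mode = c("format_independent", "format_dependent"),
                               window = c(0, 1.5), width = 0.06, step = 0.02) {
  mode <- match.arg(mode)
  bt <- bin_rates(rec, width, step, window)
  cond <- if (mode == "format_independent") bt$trials$exemplar
          else paste(bt$trials$exemplar, bt$trials$format, sep = ".")
  lev <- sort(unique(cond))
  ci <- match(cond, lev)
  G <- matrix(0, length(lev), nrow(bt$trials))
  G[cbind(ci, seq_along(ci))] <- 1
  G <- G / rowSums(G)
  nu <- dim(bt$rates)[1]; nb <- dim(bt$rates)[3]
  Fm <- matrix(NA_real_, nu, length(lev) * nb)
  for (u in seq_len(nu)) {
    m <- G %*% bt$rates[u, , ]           # cond x bins
    Fm[u, ] <- as.vector(t(m))            # time fastest within condition
  }
  rownames(Fm) <- bt$unit_ids
  structure(list(F = Fm,
                 condition = rep(lev, each = nb),
                 bin_start = rep(bt$bin_starts, times = length(lev)),
                 n_units = nu, n_conditions = length(lev),
                 n_timepoints = nb, mode = mode),
            class = "state_space_matrix")
}

#' Normalized Mahalanobis distances between condition clouds
#'
#' Per condition, the time-point columns form its sample cloud; the pooled
#' within-condition covariance `W` is ridge-regularized as
#' `W + gamma * trace(W) / N * I` (with hundreds of units `W` is otherwise
#' singular), and
#' `d(a, b) = sqrt((mu_a - mu_b)' W^-1 (mu_a - mu_b)) / N`.
#'
#' @param ssm a [state_space_matrix()].
#' @param gamma ridge weight (default 0.1).
#' @return c x c symmetric distance matrix (zero diagonal).
#' @export
condition_distances <- function(ssm, gamma = 0.1) {
  stopifnot(inherits(ssm, "state_space_matrix"))
  if (ssm$n_timepoints < 2)
    stop("each condition needs >= 2 time points: use finer binning")
  lev <- unique(ssm$condition)
  N <- ssm$n_units
  mus <- matrix(NA_real_, N, length(lev), dimnames = list(NULL, lev))
  W <- matrix(0, N, N)
  for (cl in lev) {
    Xc <- ssm$F[, ssm$condition == cl, drop = FALSE]
    mus[, cl] <- rowMeans(Xc)
    Cc <- Xc - mus[, cl]
    W <- W + tcrossprod(Cc)
  }
  W <- W / (length(lev) * (ssm$n_timepoints - 1))
  W <- W + gamma * sum(diag(W)) / N * diag(N)
  Winv_chol <- chol(W)
  D <- matrix(0, length(lev), length(lev), dimnames = list(lev, lev))
  for (i in seq_along(lev)) for (j in seq_len(i - 1L)) {
    d <- mus[, i] - mus[, j]
    z <- backsolve(Winv_chol, forwardsolve(t(Winv_chol), d))
    D[i, j] <- D[j, i] <- sqrt(sum(d * z)) / N
  }
  D
}

#' Average-linkage cluster tree with optimal leaf ordering
#'
#' UPGMA on the given distances; the leaf order minimizes the sum of
#' adjacent-leaf distances among all orders consistent with the tree
#' (exact dynamic program). Ties in merge order resolve deterministically
#' by label order.
#'
#' @param D symmetric distance matrix with labelled rows/columns.
#' @return object of class `cluster_tree`: `distances`, `hclust`,
#'   `leaf_order` (labels, optimally ordered), `newick` (merge heights as
#'   branch lengths).
#' @export
build_tree <- function(D) {
  if (!is.matrix(D) || !isSymmetric(unname(D), tol = 1e-8))
    stop("distance matrix must be symmetric")
  labels <- rownames(D) %||% paste0("c", seq_len(nrow(D)))
  dimnames(D) <- list(labels, labels)
  hc <- hclust(as.dist(D), method = "average")
  ord <- optimal_leaf_order(hc, D)
  phy <- ape::as.phylo(hc)
  structure(list(distances = D, hclust = hc,
                 leaf_order = labels[ord],
                 newick = ape::write.tree(phy)),
            class = "cluster_tree")
}

#' @export
print.cluster_tree <- function(x, ...) {
  cat("<cluster_tree (UPGMA):", paste(x$leaf_order, collapse = " | "), ">\n")
  invisible(x)
}

## Exact optimal leaf ordering (Bar-Joseph dynamic program): for each
## internal node and each (leftmost, rightmost) leaf pair, the minimum sum
## of adjacent-leaf distances of any consistent order.
optimal_leaf_order <- function(hc, D) {
  n <- nrow(D)
  leaves_of <- vector("list", nrow(hc$merge))
  costs <- vector("list", nrow(hc$merge))
  get_leaves <- function(k) if (k < 0) -k else leaves_of[[k]]
  get_cost <- function(k) {
    if (k < 0) {
      m <- matrix(0, 1, 1, dimnames = list(as.character(-k), as.character(-k)))
      return(m)
    }
    costs[[k]]
  }
  for (k in seq_len(nrow(hc$merge))) {
    a <- hc$merge[k, 1]; b <- hc$merge[k, 2]
    la <- get_leaves(a); lb <- get_leaves(b)
    ca <- get_cost(a); cb <- get_cost(b)
    all_lv <- c(la, lb)
    M <- matrix(Inf, length(all_lv), length(all_lv),
                dimnames = list(as.character(all_lv), as.character(all_lv)))
    for (u in as.character(la)) for (w in as.character(lb)) {
      ## order: u ... k | l ... w  with k in subtree a, l in subtree b
      best <- Inf
      for (kk in as.character(la)) for (ll in as.character(lb)) {
        v <- ca[u, kk] + D[as.integer(kk), as.integer(ll)] + cb[ll, w]
        if (v < best) best <- v
      }
      M[u, w] <- best
      M[w, u] <- best
    }
    leaves_of[[k]] <- all_lv
    costs[[k]] <- M
  }
  ## traceback: recursively materialize the order achieving cost M[u, w]
  order_node <- function(k, u, w) {
    if (k < 0) return(-k)
    a <- hc$merge[k, 1]; b <- hc$merge[k, 2]
    la <- get_leaves(a); lb <- get_leaves(b)
    if (u %in% lb) { tmp <- a; a <- b; b <- tmp; tmp <- la; la <- lb; lb <- tmp }
    ca <- get_cost(a); cb <- get_cost(b)
    best <- Inf; bk <- NA; bl <- NA
    for (kk in as.character(la)) for (ll in as.character(lb)) {
      v <- ca[as.character(u), kk] + D[as.integer(kk), as.integer(ll)] +
           cb[ll, as.character(w)]
      if (v < best) { best <- v; bk <- as.integer(kk); bl <- as.integer(ll) }
    }
    c(order_node(a, u, bk), order_node(b, bl, w))
  }
  root <- nrow(hc$merge)
  M <- costs[[root]]
  idx <- which(M == min(M), arr.ind = TRUE)[1, ]
  u <- as.integer(rownames(M)[idx[1]]); w <- as.integer(colnames(M)[idx[2]])
  order_node(root, u, w)
}

#' Cluster OMA exemplars in neural state space
#'
#' @param rec a main-experiment `recording_set`.
#' @param mode `"format_independent"` (7 exemplar conditions, trials
#'   pooled over formats) or `"format_dependent"` (28 exemplar x format
#'   conditions).
#' @param gamma ridge weight for the pooled covariance.
#' @inheritParams state_space_matrix
#' @return a `cluster_tree`.
#' @export
cluster_exemplars <- function(rec, mode = c("format_independent", "format_dependent"),
                              gamma = 0.1, window = c(0, 1.5),
                              width = 0.06, step = 0.02) {
  mode <- match.arg(mode)
  ssm <- state_space_matrix(rec, mode, window, width, step)
  D <- condition_distances(ssm, gamma)
  build_tree(D)
}
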