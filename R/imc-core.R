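#' Normalize single-cell protein intensities
#'
#' Applies, in order: log1p transformation, z-scoring of each marker across
#' cells, then z-scoring of each cell across markers. Zero-variance rows or
#' columns map to zeros rather than NaN, so constant markers (or cells) drop
#' out instead of poisoning downstream distances.
#'
#' @param intensities non-negative matrix, cells x markers.
#' @return numeric matrix of the same shape in normalized space.
#' @export
normalize_expression <- function(intensities) {
  if (is.null(dim(intensities)) || nrow(intensities) == 0 || ncol(intensities) == 0)
    stop("empty intensity matrix", call. = FALSE)
  if (any(intensities < 0)) stop("intensities must be non-negative", call. = FALSE)
  x <- log1p(intensities)
  x <- apply(x, 2, zscore0)                 # per marker, across cells
  x <- t(apply(x, 1, zscore0))              # per cell, across markers
  dimnames(x) <- dimnames(intensities)
  x
}

#' Phenotype cells by K-means with multiple restarts
#'
#' Runs Lloyd's K-means on the normalized matrix with `n_restarts` random
#' initializations and keeps the restart with the minimum total
#' within-cluster sum of squares. The default K of 20 reflects the panel
#' resolution this pipeline targets; many restarts make the optimum stable
#' against unlucky initialization and noisy markers.
#'
#' @param mat normalized matrix, cells x markers.
#' @param k number of clusters (default 20).
#' @param n_restarts random restarts (default 1000).
#' @param seed integer seed; the result is deterministic given the seed.
#' @param iter_max Lloyd iterations per restart.
#' @return object of class `cluster_model`: list with `k`, `centers`
#'   (k x markers), `labels` (integer per cell), `tot_withinss`, and a
#'   `markers`/`names` slot filled in by [differential_markers()].
#' @export
cluster_cells <- function(mat, k = 20, n_restarts = 1000, seed = 1, iter_max = 100) {
  stopifnot(k >= 2, n_restarts >= 1)
  if (k > nrow(mat)) stop("k exceeds the number of cells", call. = FALSE)
  fit <- with_seed(seed,
    stats::kmeans(mat, centers = k, nstart = n_restarts, iter.max = iter_max))
  structure(list(k = k, centers = fit$centers,
                 labels = unname(fit$cluster),
                 tot_withinss = fit$tot.withinss,
                 markers = NULL, cluster_names = NULL),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat("cluster_model: K =", x$k, "over", length(x$labels), "cells;",
      "within-SS =", signif(x$tot_withinss, 6), "\n")
  invisible(x)
}

#' Per-cluster differential protein markers
#'
#' For every cluster and marker, runs one-vs-one Welch t-tests against each
#' other cluster. A marker is differential for a cluster when it is
#' significant (p <= alpha) with the higher mean in that cluster in at least
#' `ceiling((K-1) * 17/19)` of the K-1 comparisons — 17 of 19 at the default
#' K = 20; the ratio is preserved for other K. Each cluster is then named by
#' the concatenation of its differential markers.
#'
#' @param model a `cluster_model`.
#' @param mat the normalized matrix the model was fit on.
#' @param alpha per-comparison significance level.
#' @return the model with `markers` (list of character vectors per cluster)
#'   and `cluster_names` filled in.
#' @export
differential_markers <- function(model, mat, alpha = 0.05) {
  K <- model$k
  stopifnot(K >= 2)
  need <- ceiling((K - 1) * 17 / 19)
  labs <- model$labels
  mnames <- colnames(mat)
  if (is.null(mnames)) mnames <- sprintf("marker_%02d", seq_len(ncol(mat)))
  # per-cluster summary stats per marker
  ns <- tabulate(labs, K)
  means <- vars <- matrix(NA_real_, K, ncol(mat))
  for (k in seq_len(K)) {
    rows <- labs == k
    if (sum(rows) >= 2) {
      means[k, ] <- colMeans(mat[rows, , drop = FALSE])
      vars[k, ] <- apply(mat[rows, , drop = FALSE], 2, stats::var)
    }
  }
  marker_sets <- vector("list", K)
  for (k in seq_len(K)) {
    if (ns[k] < 2) {
      warning("cluster ", k, " has fewer than 2 cells; no markers assigned")
      marker_sets[[k]] <- character()
      next
    }
    wins <- integer(ncol(mat))
    for (j in setdiff(seq_len(K), k)) {
      if (ns[j] < 2) next
      p <- welch_p(means[k, ], vars[k, ], ns[k], means[j, ], vars[j, ], ns[j])
      wins <- wins + as.integer(p <= alpha & means[k, ] > means[j, ])
    }
    marker_sets[[k]] <- mnames[wins >= need]
  }
  model$markers <- marker_sets
  model$cluster_names <- vapply(marker_sets, function(m)
    if (length(m)) paste(m, collapse = "_") else "unassigned", "")
  model
}

# vectorized two-sided Welch t-test p-value from summary statistics
welch_p <- function(m1, v1, n1, m2, v2, n2) {
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  p[!is.finite(p)] <- 1
  p
}
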