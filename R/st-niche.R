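#' Normalize an ST sample
#'
#' Library-size scales each in-tissue spot to the median spot total, applies
#' log1p, and then z-scales each gene across spots. The library-normalized
#' log layer is kept as `lognorm` (non-negative, used for fold changes and
#' niche expression) and the z-scaled layer as `normalized` (used for QCS).
#' Spots with zero total counts are dropped with a warning.
#'
#' @param sample an `st_sample`.
#' @return the sample with `lognorm` and `normalized` layers filled in (and
#'   zero-count spots removed from all slots).
#' @export
normalize_st <- function(sample) {
  counts <- sample$counts
  keep <- sample$coords$in_tissue == 1
  totals <- colSums(counts)
  if (any(totals[keep] == 0)) {
    warning(sum(totals[keep] == 0), " spots with zero total counts dropped")
    keep <- keep & totals > 0
  }
  counts <- counts[, keep, drop = FALSE]
  sample$coords <- sample$coords[keep, , drop = FALSE]
  sample$counts <- counts
  totals <- colSums(counts)
  sf <- stats::median(totals) / totals
  lognorm <- log1p(sweep(counts, 2, sf, `*`))
  sample$lognorm <- lognorm
  sample$normalized <- t(apply(lognorm, 1, zscore0))
  dimnames(sample$normalized) <- dimnames(lognorm)
  sample
}

#' Query co-localization score (QCS) with a permutation null
#'
#' The per-spot QCS is the mean of the scaled, log-normalized expression of
#' the query genes at the spot. Its null distribution is built by
#' independently permuting each query gene's expression vector across the
#' in-tissue spots `n_perm` times, which destroys the dependence among the
#' query genes while preserving each gene's marginal distribution. A spot is
#' significant when its empirical permutation p-value
#' `(1 + #null >= observed) / (1 + n_perm)` falls below `alpha`. The
#' per-sample summary `qcs_a` counts the significant spots.
#'
#' @param sample a normalized `st_sample`.
#' @param query character vector of query gene names (genes missing from the
#'   panel are dropped with a message; the mean is over retained genes).
#' @param n_perm permutations, default 1000.
#' @param alpha per-spot significance level, default 0.05.
#' @param seed integer seed.
#' @return list of class `qcs_result`: `sample_id`, `group`, `qcs` (per
#'   spot), `p` (per spot), `mask` (logical significance), `qcs_a`,
#'   `query_used`.
#' @export
qcs <- function(sample, query, n_perm = 1000, alpha = 0.05, seed = 1) {
  if (is.null(sample$normalized))
    stop("run normalize_st() first", call. = FALSE)
  expr <- sample$normalized
  q_used <- intersect(unique(query), rownames(expr))
  dropped <- setdiff(unique(query), q_used)
  if (length(dropped))
    message("query genes not measured, dropped: ", paste(dropped, collapse = ", "))
  if (!length(q_used)) stop("no query genes measured", call. = FALSE)
  if (length(q_used) < 2) warning("fewer than 2 query genes: degenerate null")
  qx <- expr[q_used, , drop = FALSE]
  obs <- colMeans(qx)
  n_spots <- ncol(qx)
  ge <- integer(n_spots)
  with_seed(derive_seed(seed, paste0("qcs:", sample$sample_id)), {
    for (p in seq_len(n_perm)) {
      perm <- qx
      for (g in seq_len(nrow(qx))) perm[g, ] <- qx[g, sample.int(n_spots)]
      ge <- ge + as.integer(colMeans(perm) >= obs)
    }
  })
  pv <- (1 + ge) / (1 + n_perm)
  mask <- pv < alpha
  structure(list(sample_id = sample$sample_id, group = sample$group,
                 qcs = obs, p = pv, mask = mask, qcs_a = sum(mask),
                 query_used = q_used),
            class = "qcs_result")
}

#' @export
print.qcs_result <- function(x, ...) {
  cat("qcs_result ", x$sample_id, ": ", x$qcs_a, " of ", length(x$qcs),
      " spots significant (", length(x$query_used), " query genes)\n", sep = "")
  invisible(x)
}

# mutual-rank exponentially transformed distance matrix:
# r(i,j) = 1 - q^(mutual_rank(i,j) - 1), mutual rank = geometric mean of the
# rank of j among i's Euclidean distances and vice versa
mutual_rank_dist <- function(coords, q_const = 0.95) {
  D <- as.matrix(stats::dist(coords))
  R <- t(apply(D, 1, rank, ties.method = "average"))
  # self-distance 0 occupies rank 1 in each row; subtracting 1 ranks the
  # remaining spots 1..n-1
  mr <- sqrt((R - 1) * (t(R) - 1))
  1 - q_const^(mr - 1)
}

#' Spatial clustering (silhouette coherence) of a spot mask
#'
#' Silhouette-style statistic of how spatially coherent the significant
#' spots are: for each labeled spot, `m` is its mean transformed distance to
#' the unlabeled spots and `n` its mean transformed distance to the other
#' labeled spots; the statistic averages `(m - n) / max(m, n)` over labeled
#' spots. Distances are mutual-rank transformed,
#' `r(i, j) = 1 - q^(mutual_rank - 1)`, which prioritizes local physical
#' proximity; `q` is the rank-weighting constant, 0.95 by default.
#' Values near 1 indicate a compact, coherent niche; values near 0 a random
#' scatter.
#'
#' @param coords 2-column matrix of spot coordinates (array row/col).
#' @param mask logical vector: TRUE for significant (label-1) spots.
#' @param q_const rank-weighting constant, default 0.95.
#' @return scalar delta in `[-1, 1]`.
#' @export
spatial_clustering <- function(coords, mask, q_const = 0.95) {
  mask <- as.logical(mask)
  if (sum(mask) < 2 || sum(!mask) < 2)
    stop("need at least 2 spots in each of L1 and L0", call. = FALSE)
  r <- mutual_rank_dist(coords, q_const)
  l1 <- which(mask); l0 <- which(!mask)
  m_i <- rowMeans(r[l1, l0, drop = FALSE])
  # exclude the self term: the transformed self-distance is not zero
  n_i <- (rowSums(r[l1, l1, drop = FALSE]) - r[cbind(l1, l1)]) /
    (length(l1) - 1)
  mean((m_i - n_i) / pmax(m_i, n_i))
}

#' Compare a per-sample statistic between groups
#'
#' Two-sample Welch t or Kolmogorov-Smirnov test on per-sample summaries
#' (e.g. `qcs_a` counts or spatial-clustering deltas), with a one-sided
#' option.
#'
#' @param values numeric per-sample statistic.
#' @param groups group label per sample (two groups).
#' @param test `"t"` (Welch) or `"ks"`.
#' @param alternative passed to the test; for one-sided use
#'   `"greater"`/`"less"` with groups compared in sorted label order
#'   (first sorted group minus second).
#' @return list: statistic, p_value, test, groups (sorted order used).
#' @export
compare_groups <- function(values, groups, test = c("t", "ks"),
                           alternative = "two.sided") {
  test <- match.arg(test)
  lev <- sort(unique(as.character(groups)))
  if (length(lev) != 2) stop("exactly two groups required", call. = FALSE)
  x <- values[groups == lev[1]]; y <- values[groups == lev[2]]
  if (length(x) < 2 || length(y) < 2)
    stop("need at least 2 samples per group", call. = FALSE)
  res <- if (test == "t")
    stats::t.test(x, y, alternative = alternative)
  else
    stats::ks.test(x, y, alternative = switch(alternative,
      two.sided = "two.sided", greater = "less", less = "greater"))
  list(statistic = unname(res$statistic), p_value = res$p.value,
       test = test, groups = lev)
}
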