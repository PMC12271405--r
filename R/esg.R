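#' Stratify spots into community-high and community-low sets
#'
#' The high set is the top fraction of spots by QCS, the low set the bottom
#' fraction (both 10% by default). Ties are broken by stable spot order.
#'
#' @param qcs_values numeric per-spot QCS (or a `qcs_result`).
#' @param top,bottom fractions, default 0.10 each.
#' @return list: `high`, `low` (integer spot indices).
#' @export
stratify_spots <- function(qcs_values, top = 0.10, bottom = 0.10) {
  if (inherits(qcs_values, "qcs_result")) qcs_values <- qcs_values$qcs
  n <- length(qcs_values)
  if (n < 20) stop("need at least 20 spots to stratify", call. = FALSE)
  k_hi <- max(1L, floor(n * top))
  k_lo <- max(1L, floor(n * bottom))
  if (k_hi + k_lo > n)
    stop("top and bottom fractions overlap on this sample", call. = FALSE)
  ord <- order(qcs_values, decreasing = TRUE)   # stable for ties
  list(high = sort(ord[seq_len(k_hi)]),
       low = sort(ord[seq(n - k_lo + 1L, n)]))
}

#' Per-sample extended signature genes (ESGs)
#'
#' Differential expression between community-high and community-low spots of
#' one sample: a Wilcoxon rank-sum test per gene on the log-normalized
#' layer, BH adjustment across genes, and a log2 fold-change floor computed
#' on the library-normalized layer with a small pseudocount. Only genes up
#' in the high spots are reported. Zero-variance genes are skipped.
#'
#' @param sample a normalized `st_sample`.
#' @param high,low integer spot indices from [stratify_spots()].
#' @param alpha BH-adjusted q cutoff, default 0.05.
#' @param min_lfc log2 fold-change floor, default 0.25.
#' @param pseudocount added to the mean library-normalized expression before
#'   the ratio, default 1e-9.
#' @return data.frame: gene, lfc, p, q for the selected genes.
#' @export
per_sample_esg <- function(sample, high, low, alpha = 0.05, min_lfc = 0.25,
                           pseudocount = 1e-9) {
  if (is.null(sample$lognorm)) stop("run normalize_st() first", call. = FALSE)
  if (length(high) < 5 || length(low) < 5)
    stop("need at least 5 spots per stratum", call. = FALSE)
  ln <- sample$lognorm
  libn <- expm1(ln)
  lfc <- log2((rowMeans(libn[, high, drop = FALSE]) + pseudocount) /
              (rowMeans(libn[, low, drop = FALSE]) + pseudocount))
  p <- vapply(seq_len(nrow(ln)), function(g) {
    xh <- ln[g, high]; xl <- ln[g, low]
    if (stats::sd(c(xh, xl)) == 0) return(NA_real_)
    suppressWarnings(stats::wilcox.test(xh, xl)$p.value)
  }, 0)
  q <- stats::p.adjust(p, method = "BH")
  keep <- !is.na(p) & q <= alpha & lfc >= min_lfc
  data.frame(gene = rownames(ln)[keep], lfc = lfc[keep], p = p[keep],
             q = q[keep], row.names = NULL)
}

#' Recurrent ESGs across a group's samples
#'
#' A gene is a recurrent ESG of the focal group when it appears in the
#' per-sample ESG lists of at least half the focal-group samples and its
#' focal-group fraction strictly exceeds its fraction in the other group.
#'
#' @param esg_lists named list of per-sample gene vectors (names = samples).
#' @param groups group label per sample, aligned to `esg_lists`.
#' @param focal the focal group label.
#' @return list of class `esg_set`: `recurrent` (character), `fraction`
#'   (data.frame gene, frac_focal, frac_other), `per_sample`, `focal`.
#' @export
recurrent_esgs <- function(esg_lists, groups, focal) {
  stopifnot(length(esg_lists) == length(groups))
  if (sum(groups == focal) < 2)
    stop("need at least 2 samples in the focal group", call. = FALSE)
  genes <- sort(unique(unlist(esg_lists)))
  inlist <- vapply(esg_lists, function(l) genes %in% l,
                   logical(length(genes)))
  if (length(genes) == 1) inlist <- matrix(inlist, nrow = 1)
  frac_focal <- rowMeans(inlist[, groups == focal, drop = FALSE])
  frac_other <- if (any(groups != focal))
    rowMeans(inlist[, groups != focal, drop = FALSE]) else rep(0, length(genes))
  keep <- frac_focal >= 0.5 & frac_focal > frac_other
  structure(list(recurrent = genes[keep],
                 fraction = data.frame(gene = genes, frac_focal = frac_focal,
                                       frac_other = frac_other),
                 per_sample = esg_lists, focal = focal),
            class = "esg_set")
}

#' @export
print.esg_set <- function(x, ...) {
  cat("esg_set (", x$focal, "): ", length(x$recurrent),
      " recurrent genes across ", length(x$per_sample), " samples\n", sep = "")
  invisible(x)
}

#' Cell-type specific expression of ESGs in a niche
#'
#' Projects niche-specific expression onto cell types using a single-cell
#' reference: the niche term `V_g = mean over niche spots of the expression
#' of g minus the mean over all spots`, and the projection
#' `Expr_{g,c} = AvgExpr_{g,c} * V_g`, where `AvgExpr` is the reference
#' mean expression of gene `g` in cell type `c`. Genes absent from the
#' reference are omitted with a message.
#'
#' @param genes character vector (e.g. recurrent ESGs).
#' @param reference gene x cell-type matrix of mean expression.
#' @param sample a normalized `st_sample` (uses the `lognorm` layer).
#' @param niche integer indices of the niche spots (the community-high set).
#' @return list: `expr` (gene x cell-type matrix), `v` (named niche terms),
#'   `avg` (reference rows used).
#' @export
celltype_niche_expression <- function(genes, reference, sample, niche) {
  if (is.null(sample$lognorm)) stop("run normalize_st() first", call. = FALSE)
  g_meas <- intersect(genes, rownames(sample$lognorm))
  g_use <- intersect(g_meas, rownames(reference))
  missing_ref <- setdiff(g_meas, rownames(reference))
  if (length(missing_ref))
    message("genes missing from reference omitted: ",
            paste(missing_ref, collapse = ", "))
  if (!length(g_use)) stop("reference covers none of the genes", call. = FALSE)
  ln <- sample$lognorm[g_use, , drop = FALSE]
  v <- rowMeans(ln[, niche, drop = FALSE]) - rowMeans(ln)
  avg <- reference[g_use, , drop = FALSE]
  list(expr = avg * v, v = v, avg = avg)
}

#' Per-gene validation log fold change between high and low spots
#'
#' `log2((avg_high + pc) / (avg_low + pc))` per gene on the
#' library-normalized (non-negative) layer.
#'
#' @param sample a normalized `st_sample`.
#' @param high,low spot indices.
#' @param genes genes to evaluate (defaults to all measured).
#' @param pseudocount default 1e-9.
#' @return named numeric vector of log2 fold changes (all-zero genes are
#'   excluded).
#' @export
validation_lfc <- function(sample, high, low, genes = NULL, pseudocount = 1e-9) {
  if (is.null(sample$lognorm)) stop("run normalize_st() first", call. = FALSE)
  libn <- expm1(sample$lognorm)
  if (is.null(genes)) genes <- rownames(libn)
  genes <- intersect(genes, rownames(libn))
  libn <- libn[genes, , drop = FALSE]
  nz <- rowSums(libn) > 0
  libn <- libn[nz, , drop = FALSE]
  log2((rowMeans(libn[, high, drop = FALSE]) + pseudocount) /
       (rowMeans(libn[, low, drop = FALSE]) + pseudocount))
}

#' Paired one-sided group comparison of per-gene fold changes
#'
#' Pairs genes across groups: per gene, the mean log fold change over the
#' focal-group samples is compared with the mean over the other group by a
#' paired t-test (one-sided, focal greater).
#'
#' @param lfc_matrix gene x sample matrix of log fold changes.
#' @param groups group label per sample (columns).
#' @param focal focal group label.
#' @return list: statistic, p_value, mean_diff.
#' @export
validation_group_test <- function(lfc_matrix, groups, focal) {
  a <- rowMeans(lfc_matrix[, groups == focal, drop = FALSE])
  b <- rowMeans(lfc_matrix[, groups != focal, drop = FALSE])
  tt <- stats::t.test(a, b, paired = TRUE, alternative = "greater")
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       mean_diff = mean(a - b))
}

#' Region-level niche score for compartment expression profiles
#'
#' Sums log-normalized expression over a gene set per region of interest
#' (ROI), as used for compartment-based validation panels.
#'
#' @param roi_expr ROI x gene matrix of log-normalized expression.
#' @param geneset character vector of genes.
#' @return numeric score per ROI.
#' @export
geomx_score <- function(roi_expr, geneset) {
  gs <- intersect(geneset, colnames(roi_expr))
  if (!length(gs)) stop("gene set shares no genes with the panel", call. = FALSE)
  rowSums(roi_expr[, gs, drop = FALSE])
}

#' Hypergeometric overlap test of two gene sets
#'
#' Upper-tail hypergeometric probability of observing at least the actual
#' intersection between two sets drawn from a common universe.
#'
#' @param set_a,set_b character vectors.
#' @param universe_size size of the gene universe.
#' @return list: overlap, p_value, expected.
#' @export
overlap_test <- function(set_a, set_b, universe_size) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  if (universe_size < max(length(set_a), length(set_b)))
    stop("universe smaller than one of the sets", call. = FALSE)
  k <- length(intersect(set_a, set_b))
  p <- stats::phyper(k - 1, length(set_a), universe_size - length(set_a),
                     length(set_b), lower.tail = FALSE)
  list(overlap = k, p_value = p,
       expected = length(set_a) * length(set_b) / universe_size)
}
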