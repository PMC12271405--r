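#' Ligand-receptor pairs enriched in an ESG set
#'
#' Keeps the rows of a ligand-receptor table where both the ligand and the
#' receptor gene are present in the ESG list.
#'
#' @param esg character vector of (recurrent) ESG genes, or an `esg_set`.
#' @param lr data.frame with columns `ligand` and `receptor`.
#' @return the enriched subset of `lr` (unique rows).
#' @export
lr_enrich <- function(esg, lr) {
  if (inherits(esg, "esg_set")) esg <- esg$recurrent
  keep <- lr$ligand %in% esg & lr$receptor %in% esg
  out <- unique(lr[keep, c("ligand", "receptor"), drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Cell-type interaction network from ligand-receptor pairs
#'
#' For each retained ligand-receptor pair LR and ordered cell-type pair
#' (c1, c2), the indicator `I(LR, c1, c2)` is 1 when the ligand is expressed
#' in c1 and the receptor in c2 above the threshold. With
#' `N(LR) = sum of I over all ordered pairs`, the cell-interaction score is
#' `CI(c1, c2) = sum over LR of I / N(LR)`, so each LR pair distributes one
#' unit of mass over the cell-type pairs expressing it. Pairs with N = 0
#' are dropped. "Expressed" defaults to exceeding the gene's median across
#' cell types; a numeric threshold can be supplied instead.
#'
#' @param pairs data.frame `ligand`/`receptor` (e.g. from [lr_enrich()]).
#' @param expr gene x cell-type expression matrix (e.g. the niche projection
#'   of [celltype_niche_expression()], or a reference).
#' @param threshold `"median"` (per-gene median across cell types) or a
#'   numeric cutoff applied to all genes.
#' @return list of class `ci_network`: `ci` (ordered ligand-type x
#'   receptor-type matrix), `ci_sym` (symmetrized: `ci + t(ci)` off the
#'   diagonal), `pairs_used`, `n_lr` (data.frame LR, n), `contributions`
#'   (long data.frame LR, c1, c2, weight).
#' @export
ci_network <- function(pairs, expr, threshold = "median") {
  types <- colnames(expr)
  keep <- pairs$ligand %in% rownames(expr) & pairs$receptor %in% rownames(expr)
  pairs <- unique(pairs[keep, c("ligand", "receptor"), drop = FALSE])
  thr <- if (identical(threshold, "median"))
    apply(expr, 1, stats::median)
  else
    stats::setNames(rep(threshold, nrow(expr)), rownames(expr))
  expressed <- expr > thr[rownames(expr)]
  ci <- matrix(0, length(types), length(types), dimnames = list(types, types))
  nlr <- integer(0)
  contrib <- list()
  used <- logical(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    lig <- expressed[pairs$ligand[i], ]
    rec <- expressed[pairs$receptor[i], ]
    ind <- outer(lig, rec, `&`)      # ordered: sender (ligand) x receiver
    n <- sum(ind)
    if (n == 0) next
    used[i] <- TRUE
    ci <- ci + ind / n
    lr_id <- paste(pairs$ligand[i], pairs$receptor[i], sep = "_")
    nlr[lr_id] <- n
    w <- which(ind, arr.ind = TRUE)
    contrib[[lr_id]] <- data.frame(lr = lr_id, c1 = types[w[, 1]],
                                   c2 = types[w[, 2]], weight = 1 / n)
  }
  if (!any(used)) warning("no ligand-receptor pair expressed in any cell-type pair")
  ci_sym <- ci + t(ci)
  diag(ci_sym) <- diag(ci)
  structure(list(ci = ci, ci_sym = ci_sym,
                 pairs_used = pairs[used, , drop = FALSE],
                 n_lr = data.frame(lr = names(nlr), n = unname(nlr)),
                 contributions = do.call(rbind, c(contrib,
                                                  list(make.row.names = FALSE)))),
            class = "ci_network")
}

#' @export
print.ci_network <- function(x, ...) {
  cat("ci_network: ", nrow(x$pairs_used), " LR pairs over ",
      ncol(x$ci), " cell types; total mass ", signif(sum(x$ci), 6), "\n",
      sep = "")
  invisible(x)
}
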