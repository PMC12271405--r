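#' Detect cell communities from differential interactions
#'
#' Keeps interaction pairs with BH-adjusted q below `fdr` whose coefficient
#' sign matches `direction`, builds an undirected graph over cluster nodes,
#' and takes connected components as communities. Two pruning rules are then
#' applied: (i) a component that is a single node carrying only a
#' self-interaction is removed; (ii) graph-theoretic bridge edges whose
#' removal splits a component into two sub-components of at least two nodes
#' each are removed, and components are re-extracted.
#'
#' @param diff output of [differential_interactions()] (needs cluster_a,
#'   cluster_b, coef, q).
#' @param fdr q-value cutoff, default 0.20 (the community-expansion cutoff).
#' @param direction `"positive"` keeps pairs enriched in the reference group;
#'   `"negative"` keeps depleted ones.
#' @param markers optional list of differential marker sets per cluster
#'   (from [differential_markers()]), used to annotate each community with
#'   the union of its members' markers.
#' @return list of `community` objects: `id`, `nodes`, `edges` (data.frame
#'   cluster_a/cluster_b), `markers`. Empty list (with a warning) when no
#'   pair passes the filter.
#' @export
detect_communities <- function(diff, fdr = 0.20,
                               direction = c("positive", "negative"),
                               markers = NULL) {
  direction <- match.arg(direction)
  keep <- diff$q <= fdr & if (direction == "positive") diff$coef > 0 else diff$coef < 0
  sel <- diff[keep, , drop = FALSE]
  if (nrow(sel) == 0) {
    warning("no interactions pass fdr <= ", fdr, " with ", direction, " sign")
    return(list())
  }
  # canonical order: undirected edges, sorted, so input order cannot matter
  ea <- pmin(as.character(sel$cluster_a), as.character(sel$cluster_b))
  eb <- pmax(as.character(sel$cluster_a), as.character(sel$cluster_b))
  edges <- unique(data.frame(a = ea, b = eb, stringsAsFactors = FALSE))
  edges <- edges[order(edges$a, edges$b), , drop = FALSE]
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)

  # rule (ii): iteratively drop bridges splitting off >= 2 nodes each side;
  # when several qualify, the lexicographically smallest edge goes first so
  # the result is deterministic and independent of input order
  repeat {
    br <- igraph::bridges(g)
    qual <- list()
    for (e in br) {
      g2 <- igraph::delete_edges(g, e)
      ends <- igraph::ends(g, e)
      comp <- igraph::components(g2)
      sizes <- comp$csize[comp$membership[ends]]
      if (all(sizes >= 2))
        qual[[length(qual) + 1]] <- list(e = e, key = paste(sort(ends),
                                                            collapse = "\r"))
    }
    if (!length(qual)) break
    pick <- qual[[order(vapply(qual, `[[`, "", "key"))[1]]]
    g <- igraph::delete_edges(g, pick$e)
  }
  comp <- igraph::components(g)
  out <- list()
  for (ci in seq_len(comp$no)) {
    nodes <- sort(names(comp$membership)[comp$membership == ci])
    sub <- igraph::induced_subgraph(g, nodes)
    el <- igraph::as_edgelist(sub)
    # rule (i): singleton whose only edge is a self-loop
    if (length(nodes) == 1 && all(el[, 1] == el[, 2])) next
    if (length(nodes) == 1 && nrow(el) == 0) next
    mk <- if (!is.null(markers))
      sort(unique(unlist(markers[nodes]))) else character()
    out[[length(out) + 1]] <- structure(
      list(id = NA_character_, nodes = nodes,
           edges = data.frame(cluster_a = pmin(el[, 1], el[, 2]),
                              cluster_b = pmax(el[, 1], el[, 2])),
           markers = mk),
      class = "community")
  }
  # stable ids: larger communities first, ties by first node name
  ord <- order(-vapply(out, function(cm) length(cm$nodes), 0L),
               vapply(out, function(cm) cm$nodes[1], ""))
  out <- out[ord]
  for (i in seq_along(out)) out[[i]]$id <- sprintf("community%d", i)
  out
}

#' @export
print.community <- function(x, ...) {
  cat("community ", x$id, ": nodes {", paste(x$nodes, collapse = ", "),
      "}, ", nrow(x$edges), " edges, ", length(x$markers), " markers\n",
      sep = "")
  invisible(x)
}

#' Match communities across two datasets by shared protein markers
#'
#' Each community is reduced to the union of its member clusters'
#' differential markers; the match score between two communities is the size
#' of the marker-set intersection. The assignment maximizes the total match
#' score (exact, by enumeration over the smaller side, feasible because
#' detected communities are few; a greedy best-first pass is used beyond
#' eight communities). Ties are broken by the larger community (node
#' count), then lexicographic id. Zero-score pairs stay unmatched. The
#' top-scoring match is ranked first (the "Community1" convention); with
#' only two datasets, union/split ambiguities are resolved toward the
#' highest total score.
#'
#' @param comms_a,comms_b lists of `community` objects with `markers` filled.
#' @return data.frame: id_a, id_b, score, rank (1 = top match), one row per
#'   matched pair.
#' @export
match_communities <- function(comms_a, comms_b) {
  if (!length(comms_a) || !length(comms_b))
    return(data.frame(id_a = character(), id_b = character(),
                      score = numeric(), rank = integer()))
  S <- matrix(0, length(comms_a), length(comms_b),
              dimnames = list(vapply(comms_a, `[[`, "", "id"),
                              vapply(comms_b, `[[`, "", "id")))
  for (i in seq_along(comms_a))
    for (j in seq_along(comms_b))
      S[i, j] <- length(intersect(comms_a[[i]]$markers, comms_b[[j]]$markers))
  size_a <- vapply(comms_a, function(cm) length(cm$nodes), 0L)
  size_b <- vapply(comms_b, function(cm) length(cm$nodes), 0L)
  assign_pairs <- if (min(dim(S)) <= 8)
    assignment_exact(S) else assignment_greedy(S, size_a, size_b)
  res <- lapply(seq_len(nrow(assign_pairs)), function(r) {
    i <- assign_pairs[r, 1]; j <- assign_pairs[r, 2]
    data.frame(id_a = rownames(S)[i], id_b = colnames(S)[j], score = S[i, j])
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    return(data.frame(id_a = character(), id_b = character(),
                      score = numeric(), rank = integer()))
  out <- out[order(-out$score), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

# exact maximum-total-score assignment by enumeration over the smaller side;
# only pairs with positive score are kept
assignment_exact <- function(S) {
  transposed <- nrow(S) > ncol(S)
  M <- if (transposed) t(S) else S
  n <- nrow(M); m <- ncol(M)
  best_total <- -1; best <- NULL
  cols <- seq_len(m)
  rec <- function(row, used, pairs, total) {
    # bound: remaining rows can add at most their row maxima
    if (row > n) {
      if (total > best_total) { best_total <<- total; best <<- pairs }
      return(invisible())
    }
    for (j in c(cols[!used], NA)) {
      if (is.na(j)) rec(row + 1L, used, pairs, total)
      else {
        used2 <- used; used2[j] <- TRUE
        rec(row + 1L, used2, rbind(pairs, c(row, j)), total + M[row, j])
      }
    }
  }
  rec(1L, logical(m), matrix(integer(), 0, 2), 0)
  pairs <- best
  if (is.null(pairs) || nrow(pairs) == 0) return(matrix(integer(), 0, 2))
  keep <- S[if (transposed) cbind(pairs[, 2], pairs[, 1]) else pairs] > 0
  pairs <- pairs[keep, , drop = FALSE]
  if (transposed) pairs[, 2:1, drop = FALSE] else pairs
}

# greedy best-first fallback for large instances; ties to larger communities
assignment_greedy <- function(S, size_a, size_b) {
  avail_a <- rep(TRUE, nrow(S)); avail_b <- rep(TRUE, ncol(S))
  pairs <- matrix(integer(), 0, 2)
  repeat {
    M <- S
    M[!avail_a, ] <- -1; M[, !avail_b] <- -1
    best <- max(M)
    if (best <= 0) break
    cand <- which(M == best, arr.ind = TRUE)
    sz <- size_a[cand[, 1]] + size_b[cand[, 2]]
    cand <- cand[order(-sz, rownames(S)[cand[, 1]], colnames(S)[cand[, 2]]),
                 , drop = FALSE]
    pairs <- rbind(pairs, cand[1, , drop = FALSE])
    avail_a[cand[1, 1]] <- FALSE; avail_b[cand[1, 2]] <- FALSE
  }
  pairs
}

#' Per-patient community scores and strata
#'
#' For every patient: average each pair's proximity z across the patient's
#' ROIs, sum the averages over a community's edges to get the per-community
#' score, and sum over all communities of a group to get the community-all
#' score. Patients are stratified into "high"/"low" by whether their
#' community-all score exceeds the cohort mean.
#'
#' @param interactions interaction table (roi_id, cluster_a, cluster_b, z).
#' @param communities list of `community` objects.
#' @param metadata ROI-level metadata (roi_id, patient_id).
#' @return data.frame: patient_id, one column per community id, score
#'   (community-all), stratum.
#' @export
score_patients <- function(interactions, communities, metadata) {
  md <- unique(metadata[, c("roi_id", "patient_id")])
  dat <- merge(interactions, md, by = "roi_id")
  patients <- sort(unique(metadata$patient_id))
  no_roi <- setdiff(patients, unique(dat$patient_id))
  if (length(no_roi)) {
    warning("patients without ROIs excluded: ", paste(no_roi, collapse = ", "))
    patients <- setdiff(patients, no_roi)
  }
  dat$pair <- paste(pmin(as.character(dat$cluster_a), as.character(dat$cluster_b)),
                    pmax(as.character(dat$cluster_a), as.character(dat$cluster_b)),
                    sep = "|")
  # patient x pair matrix of mean z across the patient's ROIs
  agg <- stats::aggregate(z ~ patient_id + pair, data = dat, FUN = mean)
  res <- data.frame(patient_id = patients)
  for (cm in communities) {
    pr <- paste(pmin(cm$edges$cluster_a, cm$edges$cluster_b),
                pmax(cm$edges$cluster_a, cm$edges$cluster_b), sep = "|")
    sub <- agg[agg$pair %in% pr, , drop = FALSE]
    sc <- stats::aggregate(z ~ patient_id, data = sub, FUN = sum)
    res[[cm$id]] <- sc$z[match(patients, sc$patient_id)]
    res[[cm$id]][is.na(res[[cm$id]])] <- 0
  }
  cid <- vapply(communities, `[[`, "", "id")
  res$score <- if (length(cid)) rowSums(res[, cid, drop = FALSE]) else 0
  res$stratum <- ifelse(res$score > mean(res$score), "high", "low")
  res
}
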