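# Independent oracles used across the suite. Deliberately naive: scalar
# loops and enumeration, sharing no code with the package internals.

# connected components of an undirected edge list (BFS over adjacency)
oracle_components <- function(edges) {
  nodes <- sort(unique(c(edges$a, edges$b)))
  adj <- lapply(stats::setNames(nodes, nodes), function(n)
    unique(c(edges$b[edges$a == n], edges$a[edges$b == n])))
  seen <- character()
  comps <- list()
  for (n in nodes) {
    if (n %in% seen) next
    queue <- n; comp <- character()
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (v %in% comp) next
      comp <- c(comp, v)
      queue <- c(queue, setdiff(adj[[v]], comp))
    }
    seen <- c(seen, comp)
    comps[[length(comps) + 1]] <- sort(comp)
  }
  comps
}

# community oracle: components, drop self-loop singletons, iteratively remove
# the lexicographically smallest edge whose removal splits its component into
# two parts of >= 2 nodes each
oracle_communities <- function(edges) {
  edges$a <- as.character(edges$a); edges$b <- as.character(edges$b)
  repeat {
    plain <- edges[edges$a != edges$b, , drop = FALSE]
    qual <- character()
    for (i in seq_len(nrow(plain))) {
      rest <- plain[-i, , drop = FALSE]
      # nodes of the component containing this edge, before removal
      comp_before <- NULL
      for (cp in oracle_components(plain))
        if (plain$a[i] %in% cp) comp_before <- cp
      comps_after <- oracle_components(rest)
      parts <- Filter(function(cp) any(cp %in% comp_before), comps_after)
      isolated <- setdiff(comp_before, unlist(comps_after))
      parts <- c(parts, as.list(isolated))
      if (length(parts) == 2 && all(lengths(parts) >= 2))
        qual <- c(qual, paste(plain$a[i], plain$b[i]))
    }
    if (!length(qual)) break
    drop <- sort(qual)[1]
    ab <- strsplit(drop, " ")[[1]]
    edges <- edges[!(edges$a == ab[1] & edges$b == ab[2]), , drop = FALSE]
  }
  comps <- oracle_components(edges)
  keep <- vapply(comps, function(cp) {
    if (length(cp) > 1) return(TRUE)
    has_self <- any(edges$a == cp & edges$b == cp)
    has_other <- any((edges$a == cp) != (edges$b == cp))
    !has_self && has_other
  }, TRUE)
  comps[keep]
}

# silhouette spatial coherence by scalar loops
oracle_silhouette <- function(coords, mask, q = 0.95) {
  n <- nrow(coords)
  D <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n)
    D[i, j] <- sqrt(sum((coords[i, ] - coords[j, ])^2))
  R <- matrix(0, n, n)
  for (i in 1:n) R[i, ] <- rank(D[i, ], ties.method = "average")
  r <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    mr <- sqrt((R[i, j] - 1) * (R[j, i] - 1))
    r[i, j] <- 1 - q^(mr - 1)
  }
  l1 <- which(mask); l0 <- which(!mask)
  s <- 0
  for (i in l1) {
    m_i <- mean(r[i, l0])
    n_i <- sum(r[i, setdiff(l1, i)]) / (length(l1) - 1)
    s <- s + (m_i - n_i) / max(m_i, n_i)
  }
  s / length(l1)
}

# brute-force pixel-pair count under a strict distance threshold
oracle_coloc <- function(A, B, maxdist) {
  cnt <- 0
  for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B)))
    if (sqrt(sum((A[i, ] - B[j, ])^2)) < maxdist) cnt <- cnt + 1
  cnt
}

# Cox log partial likelihood for a single covariate, no tied event times
oracle_logpl <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- which(time >= time[i])
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# product-limit survival estimate by hand; returns data.frame(time, surv)
oracle_km <- function(time, event) {
  tt <- sort(unique(time[event == 1]))
  s <- 1
  out <- data.frame(time = numeric(), surv = numeric())
  for (t in tt) {
    n_risk <- sum(time >= t)
    d <- sum(time == t & event == 1)
    s <- s * (1 - d / n_risk)
    out <- rbind(out, data.frame(time = t, surv = s))
  }
  out
}

# all permutations of a vector (tiny n)
oracle_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  do.call(c, lapply(seq_along(v), function(i)
    lapply(oracle_perms(v[-i]), function(p) c(v[i], p))))
}

# build a minimal normalized st_sample from an expression matrix, where the
# `normalized` layer is set directly (for QCS arithmetic tests)
make_st_from_normalized <- function(expr, coords = NULL) {
  if (is.null(coords))
    coords <- data.frame(barcode = paste0("b", seq_len(ncol(expr))),
                         in_tissue = 1L,
                         array_row = seq_len(ncol(expr)) - 1L,
                         array_col = 0L,
                         pxl_row_in_fullres = 0L, pxl_col_in_fullres = 0L)
  s <- st_sample("toy", "groupA", matrix(1L, nrow(expr), ncol(expr),
                                         dimnames = dimnames(expr)), coords)
  s$lognorm <- expr
  s$normalized <- expr
  s
}

# differential-interaction fixture: 10 patients/group x 2 ROIs with an
# additive group shift on the z-scores
sim_pair_z <- function(seed, shift, noise_sd = 0.5, patient_sd = 0.3,
                       n_pat = 10, rois = 2) {
  set.seed(seed)
  n <- 2 * n_pat * rois
  md <- data.frame(roi_id = sprintf("r%03d", seq_len(n)),
                   patient_id = rep(sprintf("p%02d", seq_len(2 * n_pat)), each = rois),
                   group = rep(c("groupA", "groupB"), each = n_pat * rois))
  pint <- stats::rnorm(2 * n_pat, 0, patient_sd)[rep(seq_len(2 * n_pat), each = rois)]
  tb <- data.frame(roi_id = md$roi_id, cluster_a = 1, cluster_b = 2,
                   z = pint + stats::rnorm(n, 0, noise_sd) +
                       shift * (md$group == "groupA"))
  list(table = tb, metadata = md)
}
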