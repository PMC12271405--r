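#' Delaunay spatial graph of one ROI
#'
#' Triangulates the cell centroids of a single ROI and returns the edge list.
#' Duplicate coordinates are jittered by a small epsilon (deterministically,
#' seeded by the ROI id) with a warning, since exact duplicates break the
#' triangulation.
#'
#' @param x,y cell coordinates within the ROI.
#' @param roi_id identifier used in error messages and for the jitter seed.
#' @return list of class `spatial_graph`: `roi_id`, `n` (cells), and `edges`
#'   (2-column integer matrix, `i < j`, each undirected edge once).
#' @export
build_delaunay <- function(x, y, roi_id = "roi") {
  n <- length(x)
  if (n < 3) stop("ROI ", roi_id, ": need at least 3 cells", call. = FALSE)
  if (qr(cbind(x - mean(x), y - mean(y)))$rank < 2)
    stop("ROI ", roi_id, ": all cells are collinear", call. = FALSE)
  if (anyDuplicated(cbind(x, y))) {
    warning("ROI ", roi_id, ": duplicate coordinates jittered by 1e-6")
    jit <- with_seed(derive_seed(0L, paste0("jitter:", roi_id)), {
      dup <- duplicated(cbind(x, y))
      jx <- jy <- numeric(n)
      jx[dup] <- stats::runif(sum(dup), -1e-6, 1e-6)
      jy[dup] <- stats::runif(sum(dup), -1e-6, 1e-6)
      list(jx, jy)
    })
    x <- x + jit[[1]]; y <- y + jit[[2]]
  }
  d <- deldir::deldir(x, y)
  e <- cbind(pmin(d$delsgs$ind1, d$delsgs$ind2),
             pmax(d$delsgs$ind1, d$delsgs$ind2))
  e <- unique(e)
  structure(list(roi_id = roi_id, n = n, edges = e), class = "spatial_graph")
}

#' Spatial proximity enrichment of cluster pairs in one ROI
#'
#' Counts Delaunay edges joining each (unordered) cluster pair and compares
#' the observed count with a null distribution obtained by shuffling the
#' cluster labels within the ROI `n_perm` times, keeping the graph and the
#' cluster abundances fixed. The z-score
#' `(observed - null mean) / null sd` is positive for spatially enriched
#' pairs and negative for depleted ones; it is 0 whenever the null sd is 0
#' (e.g. a single cluster in the ROI).
#'
#' @param graph a `spatial_graph` from [build_delaunay()].
#' @param labels integer or factor cluster label per cell (node).
#' @param n_perm number of label shuffles (default 1000).
#' @param seed integer seed for the shuffles.
#' @return data.frame: roi_id, cluster_a, cluster_b (a <= b), obs,
#'   null_mean, null_sd, z — one row per pair of clusters present in the ROI.
#' @export
proximity_enrichment <- function(graph, labels, n_perm = 1000, seed = 1) {
  if (length(labels) != graph$n)
    stop("labels must cover all ", graph$n, " nodes", call. = FALSE)
  if (n_perm < 100) warning("n_perm < 100 gives unstable z-scores")
  lev_orig <- sort(unique(labels))
  labels <- match(labels, lev_orig)
  C <- length(lev_orig)
  e1 <- graph$edges[, 1]; e2 <- graph$edges[, 2]
  nbin <- C * C
  key <- function(lab) {
    a <- lab[e1]; b <- lab[e2]
    (pmin(a, b) - 1L) * C + pmax(a, b)
  }
  obs <- tabulate(key(labels), nbin)
  sums <- numeric(nbin); sqs <- numeric(nbin)
  with_seed(seed, {
    for (p in seq_len(n_perm)) {
      cnt <- tabulate(key(sample(labels)), nbin)
      sums <- sums + cnt
      sqs <- sqs + cnt^2
    }
  })
  mu <- sums / n_perm
  sdv <- sqrt(pmax(sqs / n_perm - mu^2, 0) * n_perm / (n_perm - 1))
  idx <- which(upper.tri(matrix(0, C, C), diag = TRUE), arr.ind = TRUE)
  keys <- (idx[, "row"] - 1L) * C + idx[, "col"]
  z <- ifelse(sdv[keys] > 0, (obs[keys] - mu[keys]) / sdv[keys], 0)
  data.frame(roi_id = graph$roi_id,
             cluster_a = lev_orig[idx[, "row"]],
             cluster_b = lev_orig[idx[, "col"]],
             obs = obs[keys], null_mean = mu[keys], null_sd = sdv[keys],
             z = z)
}

#' Proximity enrichment across a cohort of ROIs
#'
#' Convenience wrapper running [build_delaunay()] and
#' [proximity_enrichment()] per ROI of an IMC cohort.
#'
#' @param cells data.frame with roi_id, x, y (one row per cell).
#' @param labels cluster label per cell, aligned to `cells`.
#' @param n_perm,seed passed to [proximity_enrichment()]; each ROI gets a
#'   seed derived from `seed` and its id.
#' @return row-bound interaction table over all ROIs.
#' @export
interaction_table <- function(cells, labels, n_perm = 1000, seed = 1) {
  out <- lapply(split(seq_len(nrow(cells)), cells$roi_id), function(ix) {
    g <- build_delaunay(cells$x[ix], cells$y[ix], cells$roi_id[ix[1]])
    proximity_enrichment(g, labels[ix], n_perm = n_perm,
                         seed = derive_seed(seed, paste0("perm:", cells$roi_id[ix[1]])))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# fit z ~ group + (1|patient) vs z ~ 1 + (1|patient) by ML for one pair;
# checks relaxed so the model degrades to ordinary regression with one ROI
# per patient
fit_pair_lmm <- function(df, ref_group) {
  df$grp <- factor(df$group, levels = c(setdiff(sort(unique(df$group)), ref_group),
                                        ref_group))
  ctrl <- lme4::lmerControl(check.nobs.vs.nlev = "ignore",
                            check.nobs.vs.rankZ = "ignore",
                            check.nobs.vs.nRE = "ignore",
                            check.conv.singular = "ignore",
                            calc.derivs = FALSE)
  m1 <- suppressMessages(lme4::lmer(z ~ grp + (1 | patient_id), data = df,
                                    REML = FALSE, control = ctrl))
  m0 <- suppressMessages(lme4::lmer(z ~ 1 + (1 | patient_id), data = df,
                                    REML = FALSE, control = ctrl))
  a <- suppressMessages(stats::anova(m0, m1))
  beta <- lme4::fixef(m1)[[2]]
  p <- a[["Pr(>Chisq)"]][2]
  # degenerate fits (constant response) give a zero/NaN deviance change
  if (!is.finite(p)) p <- 1
  list(coef = beta, p = p,
       ranef_var = as.data.frame(lme4::VarCorr(m1))$vcov[1])
}

#' Group-differential cell-cell interactions by random-intercept mixed model
#'
#' For each cluster pair, models the per-ROI proximity z-score as
#' `z ~ group + (1 | patient)` against the null `z ~ 1 + (1 | patient)`,
#' both fit by maximum likelihood, and tests the group effect with a
#' likelihood-ratio test. The random intercept absorbs repeated ROIs from
#' the same patient. P-values are Benjamini-Hochberg adjusted across pairs.
#' A positive coefficient means the interaction is enriched in `ref_group`.
#'
#' @param table interaction table from [interaction_table()] (or any
#'   data.frame with roi_id, cluster_a, cluster_b, z).
#' @param metadata ROI-level data.frame: roi_id, patient_id, group.
#' @param ref_group group whose enrichment gets the positive sign; defaults
#'   to the first group in sort order.
#' @param min_rois pairs observed in fewer ROIs are skipped with a warning.
#' @param one_sided also report a one-sided p (halved when the coefficient
#'   sign matches enrichment in `ref_group`, else `1 - p/2`).
#' @return data.frame: cluster_a, cluster_b, coef, ranef_var, p, q,
#'   p_one_sided, n_rois.
#' @export
differential_interactions <- function(table, metadata, ref_group = NULL,
                                      min_rois = 3, one_sided = TRUE) {
  md <- metadata[, c("roi_id", "patient_id", "group")]
  if (length(unique(md$group)) != 2)
    stop("exactly two groups are required", call. = FALSE)
  if (min(table(unique(md[, c("patient_id", "group")])$group)) < 2)
    stop("need at least 2 patients per group", call. = FALSE)
  if (is.null(ref_group)) ref_group <- sort(unique(md$group))[1]
  dat <- merge(table, md, by = "roi_id")
  keyf <- interaction(dat$cluster_a, dat$cluster_b, drop = TRUE)
  res <- lapply(split(dat, keyf), function(df) {
    if (nrow(df) < min_rois) {
      warning("pair ", df$cluster_a[1], "-", df$cluster_b[1],
              " observed in <", min_rois, " ROIs; skipped")
      return(NULL)
    }
    fit <- tryCatch(fit_pair_lmm(df, ref_group), error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    data.frame(cluster_a = df$cluster_a[1], cluster_b = df$cluster_b[1],
               coef = fit$coef, ranef_var = fit$ranef_var, p = fit$p,
               n_rois = nrow(df))
  })
  out <- do.call(rbind, res)
  if (is.null(out)) return(NULL)
  rownames(out) <- NULL
  out$q <- stats::p.adjust(out$p, method = "BH")
  if (one_sided)
    out$p_one_sided <- ifelse(out$coef > 0, out$p / 2, 1 - out$p / 2)
  out
}

#' Leave-2-patient-out subsampling confidence intervals
#'
#' Refits the mixed model of [differential_interactions()] on
#' `n_subsamples` random removals of two patients and reports the 2.5/97.5
#' percentiles of the group coefficient per pair.
#'
#' @param table interaction table.
#' @param metadata ROI-level metadata (roi_id, patient_id, group).
#' @param n_subsamples default 100.
#' @param seed integer seed for the patient draws.
#' @param ref_group as in [differential_interactions()].
#' @return data.frame: cluster_a, cluster_b, ci_lo, ci_hi, n_fits.
#' @export
leave2out_ci <- function(table, metadata, n_subsamples = 100, seed = 1,
                         ref_group = NULL) {
  md <- metadata[, c("roi_id", "patient_id", "group")]
  pat <- unique(md[, c("patient_id", "group")])
  if (length(unique(pat$group)) < 2 || min(table(pat$group)) < 4)
    stop("leave-2-out needs at least 4 patients per group", call. = FALSE)
  if (is.null(ref_group)) ref_group <- sort(unique(md$group))[1]
  dat <- merge(table, md, by = "roi_id")
  keyf <- interaction(dat$cluster_a, dat$cluster_b, drop = TRUE)
  drops <- with_seed(seed, replicate(n_subsamples,
    sample(pat$patient_id, 2), simplify = FALSE))
  res <- lapply(split(dat, keyf), function(df) {
    coefs <- vapply(drops, function(dd) {
      sub <- df[!df$patient_id %in% dd, , drop = FALSE]
      out <- tryCatch(fit_pair_lmm(sub, ref_group)$coef,
                      error = function(e) NA_real_)
      out
    }, 0)
    coefs <- coefs[is.finite(coefs)]
    data.frame(cluster_a = df$cluster_a[1], cluster_b = df$cluster_b[1],
               ci_lo = stats::quantile(coefs, 0.025, names = FALSE),
               ci_hi = stats::quantile(coefs, 0.975, names = FALSE),
               n_fits = length(coefs))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Pixel-pair co-localization count
#'
#' Number of point pairs, one from each channel, separated by a Euclidean
#' distance strictly below `maxdist` pixels. Optionally normalized per cell
#' by dividing by the number of nuclei in the image.
#'
#' @param pixels_a,pixels_b 2-column matrices of pixel coordinates.
#' @param maxdist distance threshold in pixels (default 40; a pair at
#'   exactly `maxdist` does not count).
#' @param n_nuclei if given, the count is divided by this number.
#' @return numeric: the raw count, or count / n_nuclei.
#' @export
pixel_coloc_count <- function(pixels_a, pixels_b, maxdist = 40, n_nuclei = NULL) {
  pixels_a <- as.matrix(pixels_a); pixels_b <- as.matrix(pixels_b)
  if (nrow(pixels_a) == 0 || nrow(pixels_b) == 0) return(0)
  if (any(!is.finite(pixels_a)) || any(!is.finite(pixels_b)))
    stop("coordinates must be finite", call. = FALSE)
  cnt <- 0
  chunk <- 1024L
  for (s in seq(1, nrow(pixels_a), by = chunk)) {
    ix <- s:min(s + chunk - 1L, nrow(pixels_a))
    d2 <- outer(pixels_a[ix, 1], pixels_b[, 1], "-")^2 +
          outer(pixels_a[ix, 2], pixels_b[, 2], "-")^2
    cnt <- cnt + sum(d2 < maxdist^2)
  }
  if (!is.null(n_nuclei)) cnt / n_nuclei else cnt
}
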