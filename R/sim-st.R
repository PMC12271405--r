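#' Generate synthetic Visium-style ST samples with a planted niche
#'
#' One sample per patient and group on a regular `st_grid` spot lattice.
#' Counts follow a negative-binomial baseline with gene-specific means.
#' In `groupA` samples the planted query and ESG genes are elevated by
#' `exp(niche_effect)` inside a random disc of radius `niche_radius` spots
#' (a compact niche); in `groupB` the same genes are elevated in uniformly
#' scattered spots of equal total count, emulating a diffuse pattern of the
#' same overall signal mass.
#'
#' @param config a [sim_config()].
#' @return list with `samples` (list of `st_sample` objects) and `truth`
#'   (per-sample logical niche mask over spots, plus the planted gene lists).
#' @export
gen_st_cohort <- function(config) {
  validate_sim_config(config)
  genes <- gene_names(config$n_genes)
  # cohort-level gene baseline means, shared across samples
  mu <- with_seed(derive_seed(config$seed, "st:mu"),
                  stats::rlnorm(config$n_genes, meanlog = log(2), sdlog = 1))
  names(mu) <- genes
  planted <- union(config$planted_query_genes, config$planted_esg_genes)
  rows <- config$st_grid[1]; cols <- config$st_grid[2]
  grid <- expand.grid(array_row = seq_len(rows) - 1L,
                      array_col = seq_len(cols) - 1L)
  n_spots <- nrow(grid)
  disc_n <- sum((grid$array_row - rows / 2)^2 +
                (grid$array_col - cols / 2)^2 <= config$niche_radius^2)

  samples <- list()
  masks <- list()
  for (g in c("groupA", "groupB")) {
    for (i in seq_len(config$n_patients_per_group)) {
      sample_id <- sprintf("S_%s_%02d", sub("group", "", g), i)
      sseed <- derive_seed(config$seed, paste0("st:", sample_id))
      res <- with_seed(sseed, {
        if (g == "groupA") {
          cr <- stats::runif(1, config$niche_radius, rows - 1 - config$niche_radius)
          cc <- stats::runif(1, config$niche_radius, cols - 1 - config$niche_radius)
          mask <- (grid$array_row - cr)^2 + (grid$array_col - cc)^2 <=
            config$niche_radius^2
        } else {
          mask <- rep(FALSE, n_spots)
          mask[sample.int(n_spots, disc_n)] <- TRUE
        }
        mu_mat <- matrix(mu, config$n_genes, n_spots,
                         dimnames = list(genes, NULL))
        if (length(planted) && config$niche_effect != 0)
          mu_mat[planted, mask] <- mu_mat[planted, mask] * exp(config$niche_effect)
        counts <- matrix(
          stats::rnbinom(length(mu_mat), mu = as.vector(mu_mat),
                         size = config$nb_dispersion),
          config$n_genes, n_spots, dimnames = list(genes, NULL))
        list(counts = counts, mask = mask)
      })
      coords <- data.frame(
        barcode = sprintf("%s_BC%04d", sample_id, seq_len(n_spots)),
        in_tissue = 1L,
        array_row = grid$array_row, array_col = grid$array_col,
        pxl_row_in_fullres = grid$array_row * 100L,
        pxl_col_in_fullres = grid$array_col * 100L
      )
      colnames(res$counts) <- coords$barcode
      samples[[sample_id]] <- st_sample(sample_id, g, res$counts, coords)
      masks[[sample_id]] <- res$mask
    }
  }
  list(samples = samples,
       truth = list(niche_mask = masks,
                    query_genes = config$planted_query_genes,
                    esg_genes = config$planted_esg_genes))
}

#' Construct an ST sample container
#'
#' @param sample_id sample identifier.
#' @param group group label.
#' @param counts gene x spot matrix of non-negative integer counts.
#' @param coords data.frame with columns barcode, in_tissue, array_row,
#'   array_col, pxl_row_in_fullres, pxl_col_in_fullres (tissue_positions
#'   convention).
#' @return object of class `st_sample`.
#' @export
st_sample <- function(sample_id, group, counts, coords) {
  stopifnot(ncol(counts) == nrow(coords), all(counts >= 0))
  structure(list(sample_id = sample_id, group = group,
                 counts = counts, coords = coords,
                 lognorm = NULL, normalized = NULL),
            class = "st_sample")
}

#' @export
print.st_sample <- function(x, ...) {
  cat("st_sample ", x$sample_id, " (", x$group, "): ",
      nrow(x$counts), " genes x ", ncol(x$counts), " spots",
      if (!is.null(x$normalized)) ", normalized" else "", "\n", sep = "")
  invisible(x)
}

#' Generate a synthetic cell-type reference and ligand-receptor table
#'
#' The reference is a gene x cell-type matrix of mean expression in which
#' each cell type has ten designated marker genes whose mean is highest in
#' that type. The ligand-receptor table lists unique gene pairs from the
#' universe; roughly one fifth of the pairs are embedded in the planted ESG
#' genes (both ligand and receptor) so that niche-level LR enrichment has a
#' ground truth.
#'
#' @param config a [sim_config()].
#' @return list with `reference` (gene x cell-type matrix), `lr`
#'   (data.frame ligand/receptor), `markers` (list of marker genes per type),
#'   and `planted_lr` (the LR rows embedded in planted ESGs).
#' @export
gen_reference_and_lr <- function(config) {
  validate_sim_config(config)
  if (config$n_celltypes < 2) stop("need at least 2 cell types", call. = FALSE)
  genes <- gene_names(config$n_genes)
  base_types <- c("CAF", "Endothelial", "Macrophage", "Tcell", "Tumor",
                  "Neutrophil", "Bcell", "DC")
  types <- if (config$n_celltypes <= length(base_types))
    base_types[seq_len(config$n_celltypes)]
  else sprintf("celltype%02d", seq_len(config$n_celltypes))

  with_seed(derive_seed(config$seed, "reference"), {
    ref <- matrix(stats::rlnorm(config$n_genes * length(types), 0, 0.5),
                  config$n_genes, length(types),
                  dimnames = list(genes, types))
    marker_pool <- sample(genes, 10 * length(types))
    markers <- split(marker_pool, rep(types, each = 10))[types]
    for (ty in types) ref[markers[[ty]], ty] <- ref[markers[[ty]], ty] * 5 + 5

    esg <- config$planted_esg_genes
    planted_lr <- NULL
    n_plant <- if (length(esg) >= 2) min(config$n_lr_pairs %/% 5,
                                         length(esg) %/% 2) else 0
    if (n_plant > 0) {
      pick <- sample(esg, 2 * n_plant)
      planted_lr <- data.frame(ligand = pick[seq_len(n_plant)],
                               receptor = pick[n_plant + seq_len(n_plant)])
    }
    lr <- planted_lr
    while (is.null(lr) || nrow(lr) < config$n_lr_pairs) {
      cand <- data.frame(ligand = sample(genes, config$n_lr_pairs, replace = TRUE),
                         receptor = sample(genes, config$n_lr_pairs, replace = TRUE))
      cand <- cand[cand$ligand != cand$receptor, , drop = FALSE]
      lr <- unique(rbind(lr, cand))
    }
    lr <- lr[seq_len(config$n_lr_pairs), , drop = FALSE]
    rownames(lr) <- NULL
    list(reference = ref, lr = lr, markers = markers, planted_lr = planted_lr)
  })
}

#' Generate survival outcomes tied to a patient-level score
#'
#' Event times are exponential with hazard `h0 * hazard_ratio^z`, where `z`
#' is the standardized score, so `log(hazard_ratio)` is the true log-hazard
#' coefficient per score standard deviation. Censoring is independent
#' exponential with per-subject rate chosen so the expected censored fraction
#' equals `censoring_fraction`.
#'
#' @param scores named numeric vector of per-patient scores (names are
#'   patient ids).
#' @param config a [sim_config()]; uses `seed`, `hazard_ratio`,
#'   `censoring_fraction`.
#' @param baseline_median median survival (months) at the average score.
#' @return data.frame: patient_id, time (months), event (0/1).
#' @export
gen_survival <- function(scores, config, baseline_median = 36) {
  if (any(!is.finite(scores))) stop("scores must be finite", call. = FALSE)
  z <- if (stats::sd(scores) > 0) as.vector(scale(scores)) else rep(0, length(scores))
  h0 <- log(2) / baseline_median
  rate <- h0 * config$hazard_ratio^z
  with_seed(derive_seed(config$seed, "survival"), {
    t_event <- stats::rexp(length(rate), rate)
    if (config$censoring_fraction > 0) {
      cf <- config$censoring_fraction
      t_cens <- stats::rexp(length(rate), rate * cf / (1 - cf))
      data.frame(patient_id = names(scores),
                 time = pmin(t_event, t_cens),
                 event = as.integer(t_event <= t_cens))
    } else {
      data.frame(patient_id = names(scores), time = t_event,
                 event = 1L)
    }
  })
}
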