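#' Simulation configuration for synthetic spatial-omics cohorts
#'
#' Bundles every knob of the synthetic-data generators into one validated
#' object. A fixed `seed` makes all generators byte-reproducible.
#'
#' Defaults emulate the study conditions the pipeline is designed for:
#' two patient groups ("groupA" and "groupB"), two 600x600 micron regions of
#' interest (ROIs) per patient with ~500 segmented cells each, a 26-marker
#' protein panel phenotyped into 20 clusters, and 40x40-spot spatial
#' transcriptomics (ST) arrays with a few hundred genes. Planted structure
#' (spatially adjacent cluster pairs, a compact co-expression niche,
#' score-linked hazards) gives every downstream stage a ground truth.
#'
#' @param seed integer random seed.
#' @param n_patients_per_group patients per group.
#' @param rois_per_patient ROIs imaged per patient.
#' @param cells_per_roi cells segmented per ROI.
#' @param n_markers protein markers on the panel.
#' @param n_clusters true cell phenotypes.
#' @param planted_pairs list of lists with fields `a`, `b` (cluster indices),
#'   `group` (group label whose patients carry the adjacency), and `strength`
#'   in `[0,1]`: the probability that a cell of cluster `b` is seeded within
#'   one Delaunay neighborhood of a cluster-`a` partner.
#' @param roi_size side of the square ROI, microns.
#' @param st_grid integer `(rows, cols)` of the ST spot lattice.
#' @param n_genes size of the ST gene universe (genes named `g0001`, ...).
#' @param niche_radius radius, in spots, of the planted niche disc.
#' @param planted_query_genes,planted_esg_genes gene names elevated inside the
#'   niche; the query genes stand for the community-derived query, the ESG
#'   genes for co-expressed extended signature genes.
#' @param niche_effect log-fold elevation of the planted genes in niche spots.
#' @param nb_dispersion negative-binomial size parameter of ST counts.
#' @param hazard_ratio hazard ratio per standard deviation of community score.
#' @param censoring_fraction expected fraction of censored patients.
#' @param n_celltypes cell types in the synthetic single-cell reference.
#' @param n_lr_pairs rows of the synthetic ligand-receptor table.
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       n_patients_per_group = 10L,
                       rois_per_patient = 2L,
                       cells_per_roi = 500L,
                       n_markers = 26L,
                       n_clusters = 20L,
                       planted_pairs = list(),
                       roi_size = 600,
                       st_grid = c(40L, 40L),
                       n_genes = 500L,
                       niche_radius = 7,
                       planted_query_genes = character(),
                       planted_esg_genes = character(),
                       niche_effect = 1.5,
                       nb_dispersion = 2,
                       hazard_ratio = 3,
                       censoring_fraction = 0.3,
                       n_celltypes = 5L,
                       n_lr_pairs = 50L) {
  cfg <- list(
    seed = as.integer(seed),
    n_patients_per_group = as.integer(n_patients_per_group),
    rois_per_patient = as.integer(rois_per_patient),
    cells_per_roi = as.integer(cells_per_roi),
    n_markers = as.integer(n_markers),
    n_clusters = as.integer(n_clusters),
    planted_pairs = planted_pairs,
    roi_size = roi_size,
    st_grid = as.integer(st_grid),
    n_genes = as.integer(n_genes),
    niche_radius = niche_radius,
    planted_query_genes = planted_query_genes,
    planted_esg_genes = planted_esg_genes,
    niche_effect = niche_effect,
    nb_dispersion = nb_dispersion,
    hazard_ratio = hazard_ratio,
    censoring_fraction = censoring_fraction,
    n_celltypes = as.integer(n_celltypes),
    n_lr_pairs = as.integer(n_lr_pairs)
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_clusters >= 2, cfg$n_patients_per_group >= 1,
            cfg$rois_per_patient >= 1, length(cfg$st_grid) == 2)
  for (pp in cfg$planted_pairs) {
    if (!all(c("a", "b", "group", "strength") %in% names(pp)))
      stop("each planted pair needs fields a, b, group, strength", call. = FALSE)
    if (pp$strength < 0 || pp$strength > 1)
      stop("planted-pair adjacency strength must lie in [0,1]", call. = FALSE)
    if (pp$a > cfg$n_clusters || pp$b > cfg$n_clusters)
      stop("planted pair references a cluster beyond n_clusters", call. = FALSE)
  }
  gene_universe <- gene_names(cfg$n_genes)
  bad <- setdiff(c(cfg$planted_query_genes, cfg$planted_esg_genes), gene_universe)
  if (length(bad))
    stop("planted gene lists exceed the gene universe: ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (cfg$hazard_ratio <= 0) stop("hazard_ratio must be positive", call. = FALSE)
  if (cfg$censoring_fraction < 0 || cfg$censoring_fraction >= 1)
    stop("censoring_fraction must lie in [0,1)", call. = FALSE)
  if (cfg$niche_radius >= min(cfg$st_grid) / 2)
    stop("niche_radius must be smaller than half the grid", call. = FALSE)
  invisible(cfg)
}

gene_names <- function(n) sprintf("g%04d", seq_len(n))

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config: ", x$n_patients_per_group, " patients/group x ",
      x$rois_per_patient, " ROIs x ", x$cells_per_roi, " cells; ",
      x$n_markers, " markers, ", x$n_clusters, " clusters; ST ",
      x$st_grid[1], "x", x$st_grid[2], " spots, ", x$n_genes, " genes; seed ",
      x$seed, "\n", sep = "")
  invisible(x)
}
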