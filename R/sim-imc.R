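#' Generate a synthetic multi-patient IMC cohort with planted adjacency
#'
#' Emulates an imaging-mass-cytometry cohort: two patient groups, several
#' square ROIs per patient, and per-cell protein intensities drawn from
#' cluster archetypes with log-normal noise. Each cluster has two designated
#' archetype markers with elevated mean intensity. In the group named by a
#' planted pair, cells of cluster `b` are seeded, with probability
#' `strength`, within one Delaunay-neighborhood distance of a random cluster
#' `a` cell, creating genuine spatial adjacency between the two phenotypes;
#' all other placements are uniform over the ROI square.
#'
#' @param config a [sim_config()].
#' @return list with elements
#'   \describe{
#'     \item{cells}{data.frame: cell_id, roi_id, patient_id, group, x, y.}
#'     \item{intensities}{matrix (cells x markers) of raw intensities,
#'       rows aligned to `cells`.}
#'     \item{metadata}{patient-level data.frame: patient_id, group, age,
#'       stage, bmi.}
#'     \item{roi_meta}{ROI-level data.frame: roi_id, patient_id, group.}
#'     \item{truth}{ground truth: `labels` (true cluster per cell),
#'       `planted_pairs`, `archetype_markers` (list per cluster).}
#'   }
#' @export
gen_imc_cohort <- function(config) {
  validate_sim_config(config)
  if (config$cells_per_roi < 10 * config$n_clusters)
    stop("cells_per_roi must be at least 10 * n_clusters", call. = FALSE)
  K <- config$n_clusters
  M <- config$n_markers
  markers <- sprintf("marker_%02d", seq_len(M))
  # two archetype markers per cluster, cycling over the panel
  arch <- lapply(seq_len(K), function(k) {
    idx <- ((2 * (k - 1)) %% M) + c(1L, 2L)
    idx[idx > M] <- idx[idx > M] - M
    markers[idx]
  })
  groups <- c("groupA", "groupB")
  # typical nearest-neighbour spacing in a uniform ROI; partners are seeded
  # within this radius so they fall inside one Delaunay neighbourhood
  near_r <- 0.5 * config$roi_size / sqrt(config$cells_per_roi)

  cells_list <- list()
  int_list <- list()
  lab_list <- list()
  pat_rows <- list()
  roi_rows <- list()
  for (g in groups) {
    pairs_g <- Filter(function(p) p$group == g, config$planted_pairs)
    for (i in seq_len(config$n_patients_per_group)) {
      patient_id <- sprintf("P_%s_%02d", sub("group", "", g), i)
      pseed <- derive_seed(config$seed, paste0("pat:", patient_id))
      pat_rows[[patient_id]] <- with_seed(pseed, data.frame(
        patient_id = patient_id, group = g,
        age = round(stats::rnorm(1, 58, 10)),
        stage = sample(1:3, 1),
        bmi = round(stats::rnorm(1, 28, 4), 1)
      ))
      for (r in seq_len(config$rois_per_patient)) {
        roi_id <- sprintf("%s_R%d", patient_id, r)
        rseed <- derive_seed(config$seed, paste0("roi:", roi_id))
        roi <- with_seed(rseed,
          sim_one_roi(config, K, near_r, pairs_g, markers, arch))
        n <- nrow(roi$pos)
        cells_list[[roi_id]] <- data.frame(
          cell_id = sprintf("%s_c%04d", roi_id, seq_len(n)),
          roi_id = roi_id, patient_id = patient_id, group = g,
          x = roi$pos[, 1], y = roi$pos[, 2]
        )
        int_list[[roi_id]] <- roi$intensity
        lab_list[[roi_id]] <- roi$labels
        roi_rows[[roi_id]] <- data.frame(roi_id = roi_id,
                                         patient_id = patient_id, group = g)
      }
    }
  }
  cells <- do.call(rbind, cells_list)
  rownames(cells) <- NULL
  intensities <- do.call(rbind, int_list)
  rownames(intensities) <- cells$cell_id
  list(
    cells = cells,
    intensities = intensities,
    metadata = do.call(rbind, c(pat_rows, list(make.row.names = FALSE))),
    roi_meta = do.call(rbind, c(roi_rows, list(make.row.names = FALSE))),
    truth = list(labels = unlist(lab_list, use.names = FALSE),
                 planted_pairs = config$planted_pairs,
                 archetype_markers = arch)
  )
}

# one ROI: labels, positions (with planted adjacency), intensities
sim_one_roi <- function(config, K, near_r, pairs_g, markers, arch) {
  n <- config$cells_per_roi
  labels <- sample.int(K, n, replace = TRUE)
  pos <- cbind(stats::runif(n, 0, config$roi_size),
               stats::runif(n, 0, config$roi_size))
  for (pp in pairs_g) {
    ia <- which(labels == pp$a)
    ib <- which(labels == pp$b)
    if (!length(ia) || !length(ib)) next
    move <- ib[stats::runif(length(ib)) < pp$strength]
    if (!length(move)) next
    anchor <- ia[sample.int(length(ia), length(move), replace = TRUE)]
    ang <- stats::runif(length(move), 0, 2 * pi)
    rad <- stats::runif(length(move), 0, near_r)
    pos[move, 1] <- pmin(pmax(pos[anchor, 1] + rad * cos(ang), 0), config$roi_size)
    pos[move, 2] <- pmin(pmax(pos[anchor, 2] + rad * sin(ang), 0), config$roi_size)
  }
  meanlog <- matrix(0, n, config$n_markers, dimnames = list(NULL, markers))
  for (k in seq_len(K)) {
    rows <- labels == k
    if (any(rows)) meanlog[rows, arch[[k]]] <- 1.5
  }
  intensity <- matrix(
    stats::rlnorm(n * config$n_markers, meanlog = as.vector(meanlog), sdlog = 0.4),
    n, config$n_markers, dimnames = list(NULL, markers))
  list(labels = labels, pos = pos, intensity = intensity)
}
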