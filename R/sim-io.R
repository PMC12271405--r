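#' Write an IMC cohort to disk as plain-text tables
#'
#' Writes one TSV of cells (cell_id, roi_id, patient_id, x, y,
#' marker_1..marker_M), one patient metadata CSV, and optionally the ground
#' truth as JSON.
#'
#' @param cohort output of [gen_imc_cohort()].
#' @param dir output directory (created if missing).
#' @param truth write `truth.json` as well.
#' @return `dir`, invisibly.
#' @export
write_imc_cohort <- function(cohort, dir, truth = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tab <- cbind(cohort$cells, as.data.frame(cohort$intensities))
  utils::write.table(tab, file.path(dir, "cells.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.csv(cohort$metadata, file.path(dir, "metadata.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$roi_meta, file.path(dir, "roi_meta.csv"),
                   row.names = FALSE)
  if (truth)
    jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read an IMC cell table written by [write_imc_cohort()]
#'
#' Accepts any TSV with the same header contract: cell_id, roi_id,
#' patient_id, x, y followed by marker columns.
#'
#' @param path path to the cells TSV.
#' @return list with `cells` (coordinates and ids) and `intensities` matrix.
#' @export
read_imc_cells <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE)
  id_cols <- intersect(c("cell_id", "roi_id", "patient_id", "group", "x", "y"),
                       colnames(tab))
  marker_cols <- setdiff(colnames(tab), id_cols)
  intensities <- as.matrix(tab[, marker_cols, drop = FALSE])
  rownames(intensities) <- tab$cell_id
  list(cells = tab[, id_cols, drop = FALSE], intensities = intensities)
}

#' Write an ST sample in the 10X Visium layout
#'
#' Emits `matrix.mtx`, `features.tsv`, `barcodes.tsv` and
#' `tissue_positions.csv` under `dir`.
#'
#' @param sample an `st_sample`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_visium <- function(sample, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- Matrix::Matrix(sample$counts, sparse = TRUE)
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  feats <- data.frame(id = rownames(sample$counts),
                      name = rownames(sample$counts),
                      type = "Gene Expression")
  utils::write.table(feats, file.path(dir, "features.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeLines(colnames(sample$counts), file.path(dir, "barcodes.tsv"))
  utils::write.csv(sample$coords, file.path(dir, "tissue_positions.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read an ST sample from a 10X Visium-layout directory
#'
#' @param dir directory holding matrix.mtx, features.tsv, barcodes.tsv and
#'   tissue_positions.csv.
#' @param sample_id,group identifiers attached to the returned object.
#' @return an `st_sample`.
#' @export
read_visium <- function(dir, sample_id = basename(dir), group = NA_character_) {
  m <- as.matrix(Matrix::readMM(file.path(dir, "matrix.mtx")))
  feats <- utils::read.delim(file.path(dir, "features.tsv"), header = FALSE)
  barcodes <- readLines(file.path(dir, "barcodes.tsv"))
  coords <- utils::read.csv(file.path(dir, "tissue_positions.csv"))
  dimnames(m) <- list(feats[[1]], barcodes)
  coords <- coords[match(barcodes, coords$barcode), , drop = FALSE]
  st_sample(sample_id, group, m, coords)
}
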