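#' @keywords internal
"_PACKAGE"

# Derive a reproducible child seed from a parent seed and a string tag.
# Keeps results stable under partial regeneration (one stream per
# patient/ROI/sample) and stays below 2^31.
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(paste0(tag, ":", seed)) * seq_along(utf8ToInt(paste0(tag, ":", seed))))
  as.integer((seed * 48271 + h) %% .Machine$integer.max)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# z-score a vector; zero-variance vectors map to zeros
zscore0 <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

#' Read a GMT gene-set file
#'
#' @param path path to a tab-separated GMT file (name, description, genes...).
#' @return named list of character vectors of gene names.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    parts[-(1:2)]
  })
  names(out) <- vapply(lines, function(l) strsplit(l, "\t", fixed = TRUE)[[1]][1], "")
  out
}

#' Write gene sets to a GMT file
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, nm, sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
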