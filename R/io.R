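# Plain-text I/O: cohort tables and metabolite matrices as CSV, spectra as
# two-column ppm/intensity text (an XY dialect in the JCAMP-DX spirit).

#' Write / read a cohort table
#'
#' One row per specimen with percent tissue columns, as produced by
#' [generate_cohort()].
#'
#' @param cohort cohort `data.frame`.
#' @param path file path.
#' @return `read_cohort_csv` returns the cohort `data.frame`.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  out$location <- factor(out$location, levels = LOCATIONS)
  out$grade <- factor(out$grade, levels = c("I", "II", "III", "missing"))
  out$fibrosis_grade <- factor(as.character(out$fibrosis_grade),
                               levels = c("1", "2", "3", "none"))
  class(out) <- c("stromanmr_cohort", "data.frame")
  out
}

#' Write / read a spectrum as two-column XY text
#'
#' Header lines start with `##`; data lines are `ppm<TAB>intensity` in axis
#' order.
#'
#' @param spectrum a `stromanmr_spectrum`.
#' @param path file path.
#' @return `read_spectrum_xy` returns a `stromanmr_spectrum`.
#' @export
write_spectrum_xy <- function(spectrum, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("## sample_id=%s", spectrum$sample_id),
               sprintf("## weight_mg=%.6g", spectrum$weight_mg),
               "## columns=ppm intensity"), con)
  utils::write.table(cbind(spectrum$ppm, spectrum$intensity), con,
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_spectrum_xy
#' @export
read_spectrum_xy <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^##", lines)
  meta <- lines[hdr]
  get <- function(key) {
    m <- grep(sprintf("^## %s=", key), meta, value = TRUE)
    if (length(m)) sub(sprintf("^## %s=", key), "", m[1]) else NA
  }
  xy <- utils::read.table(text = lines[!hdr], sep = "\t",
                          col.names = c("ppm", "intensity"))
  new_spectrum(xy$ppm, xy$intensity, sample_id = get("sample_id"),
               weight_mg = as.numeric(get("weight_mg")))
}

#' Write / read a metabolite matrix as CSV
#'
#' Values with a `sample_id` first column; scaling metadata is not
#' serialized (matrices are written in `raw` or `weight_normalized` state).
#'
#' @param matrix a `metabolite_matrix` (or plain matrix).
#' @param path file path.
#' @return `read_matrix_csv` returns a raw `metabolite_matrix`.
#' @export
write_matrix_csv <- function(matrix, path) {
  v <- if (inherits(matrix, "metabolite_matrix")) matrix$values else matrix
  df <- data.frame(sample_id = rownames(v), v, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_csv
#' @export
read_matrix_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  v <- as.matrix(df[, -1, drop = FALSE])
  rownames(v) <- df$sample_id
  metabolite_matrix(v)
}
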