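#' Read and write abundance matrices and sample metadata
#'
#' Plain tabular text, accession-keyed rows — the dialect of label-free
#' quantitation exports. The first column holds protein accessions;
#' remaining columns are samples. Metadata tables carry `sample`,
#' `genotype`, `age`, `sex`, `run_order`, `tissue`.
#'
#' @param mat Protein x sample matrix.
#' @param path File path (`.csv` or `.tsv` decides the separator).
#' @return Readers return the matrix / data frame.
#' @export
write_abundance_matrix <- function(mat, path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- data.frame(accession = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_abundance_matrix
#' @export
read_abundance_matrix <- function(path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  storage.mode(mat) <- "double"
  mat
}

#' @rdname write_abundance_matrix
#' @param metadata Sample metadata data frame.
#' @export
write_sample_metadata <- function(metadata, path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  utils::write.table(metadata, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_abundance_matrix
#' @export
read_sample_metadata <- function(path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  utils::read.table(path, sep = sep, header = TRUE,
                    stringsAsFactors = FALSE)
}

#' Write and read chromatograms as long-format tabular text
#'
#' Columns: `fragment`, `label`, `time` (min), `intensity`.
#'
#' @param chrom A `chromatogram_set`.
#' @param path CSV path.
#' @export
write_chromatograms <- function(chrom, path) {
  utils::write.csv(chrom, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_chromatograms
#' @export
read_chromatograms <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(out) <- c("chromatogram_set", "data.frame")
  out
}
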