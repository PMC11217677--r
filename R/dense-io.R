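#' Read a dense contact matrix from a text file
#'
#' Reads a whitespace-delimited square numeric matrix (no header). Gzipped
#' files (`.gz`) are read transparently. Non-finite entries become missing.
#' Intended for fixtures and interoperability with matrix dumps.
#'
#' @param path Path to a TSV (optionally gzip-compressed) square matrix.
#' @param resolution Binning resolution in bp.
#' @param chrom Chromosome name to attach.
#' @param sample_id Sample identifier; defaults to the file name.
#' @return A [contact_matrix()].
#' @export
load_dense <- function(path, resolution, chrom = "chrS",
                       sample_id = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  vals <- as.matrix(utils::read.table(path, header = FALSE,
                                      colClasses = "numeric"))
  dimnames(vals) <- NULL
  if (nrow(vals) != ncol(vals)) {
    stop("dense matrix in ", basename(path), " is not square (",
         nrow(vals), " x ", ncol(vals), ")", call. = FALSE)
  }
  contact_matrix(vals, resolution, chrom = chrom, sample_id = sample_id)
}

#' Write a dense contact matrix to a text file
#'
#' Inverse of [load_dense()]: writes the values as a headerless
#' tab-separated matrix. Missing entries are written as `NA`. A `.gz` suffix
#' triggers gzip compression.
#'
#' @param m A [contact_matrix()] or plain numeric matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dense <- function(m, path) {
  vals <- if (inherits(m, "contact_matrix")) m$values else as.matrix(m)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(vals, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}
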