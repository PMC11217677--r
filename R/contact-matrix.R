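#' Construct a contact matrix object
#'
#' A `contact_matrix` holds a dense, square, symmetric intrachromosomal
#' contact matrix (raw counts or balanced values, missing entries as `NA`),
#' together with its bin table, binning resolution and a retained-bin mask
#' over the chromosome's original binning.
#'
#' @param values Square numeric matrix; non-negative or `NA`. Non-finite
#'   entries are converted to `NA`.
#' @param resolution Binning resolution in bp.
#' @param chrom Chromosome name.
#' @param bins Optional bin table (tibble with `chrom`, `start`, `end`,
#'   `index`); built from `resolution` when absent. `index` is the 0-based
#'   position of each bin in the chromosome's original binning.
#' @param retained_mask Logical vector over the original bins; `TRUE` entries
#'   correspond, in order, to the rows of `values`. Defaults to all `TRUE`.
#' @param sample_id Free-text sample identifier.
#' @param balanced Whether `values` carry balancing weights.
#' @return An object of class `contact_matrix`.
#' @export
contact_matrix <- function(values, resolution, chrom = "chrS",
                           bins = NULL, retained_mask = NULL,
                           sample_id = "sample", balanced = FALSE) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("contact matrix must be square", call. = FALSE)
  storage.mode(values) <- "double"
  values[!is.finite(values)] <- NA_real_
  if (any(values < 0, na.rm = TRUE)) stop("contact matrix entries must be non-negative", call. = FALSE)
  fin <- !is.na(values)
  if (any(fin != t(fin)) ||
      max(abs(values[fin & t(fin)] - t(values)[fin & t(fin)]), 0) > 1e-8) {
    stop("contact matrix must be symmetric", call. = FALSE)
  }
  n <- nrow(values)
  if (is.null(retained_mask)) retained_mask <- rep(TRUE, n)
  if (sum(retained_mask) != n) {
    stop("retained_mask must have exactly nrow(values) TRUE entries", call. = FALSE)
  }
  if (is.null(bins)) {
    idx <- which(retained_mask) - 1L
    bins <- tibble::tibble(chrom = chrom,
                           start = idx * as.numeric(resolution),
                           end = (idx + 1) * as.numeric(resolution),
                           index = idx)
  }
  stopifnot(nrow(bins) == n, all(diff(bins$index) > 0))
  structure(list(values = values, bins = bins,
                 resolution = as.numeric(resolution),
                 retained_mask = retained_mask, chrom = chrom,
                 sample_id = sample_id, balanced = isTRUE(balanced)),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("<contact_matrix> %s %s: %d x %d bins @ %s bp (%s)%s\n",
              x$sample_id, x$chrom, nrow(x$values), ncol(x$values),
              format(x$resolution, big.mark = ","),
              if (x$balanced) "balanced" else "raw",
              if (all(x$retained_mask)) "" else
                sprintf(", %d of %d bins retained",
                        sum(x$retained_mask), length(x$retained_mask))))
  invisible(x)
}

#' @export
dim.contact_matrix <- function(x) dim(x$values)

#' Extract the dense matrix from a contact_matrix
#' @param x A `contact_matrix`.
#' @param ... Unused.
#' @export
as.matrix.contact_matrix <- function(x, ...) x$values

empty_bin_rows <- function(values) {
  # empty: every entry in the row is zero or missing
  apply(values, 1L, function(r) all(is.na(r) | r == 0))
}

#' Drop empty bins from a contact matrix
#'
#' Removes every bin whose entire row (equivalently column, by symmetry) is
#' zero or missing: the standard treatment of unmappable or unsequenced loci.
#' The retained-bin mask and bin table are updated accordingly. Idempotent.
#'
#' @param m A [contact_matrix()].
#' @return A `contact_matrix` with no all-empty rows.
#' @export
exclude_empty_bins <- function(m) {
  stopifnot(inherits(m, "contact_matrix"))
  empty <- empty_bin_rows(m$values)
  if (all(empty)) stop("empty matrix", call. = FALSE)
  if (!any(empty)) return(m)
  keep <- !empty
  mask <- m$retained_mask
  mask[which(mask)[empty]] <- FALSE
  contact_matrix(m$values[keep, keep, drop = FALSE], m$resolution,
                 chrom = m$chrom, bins = m$bins[keep, , drop = FALSE],
                 retained_mask = mask, sample_id = m$sample_id,
                 balanced = m$balanced)
}

#' Restrict matrices to their common non-empty bins
#'
#' When comparing contact matrices, bins are excluded from the calculation if
#' they are empty in any of the matrices of interest: this restricts all
#' inputs to the intersection of their non-empty bin sets so the window
#' geometry is identical across the comparison.
#'
#' @param matrices A list of [contact_matrix()] objects on the same chromosome
#'   with the same resolution and original bin count.
#' @return A list of `contact_matrix` objects with identical retained masks.
#' @export
intersect_nonempty <- function(matrices) {
  stopifnot(is.list(matrices), length(matrices) >= 1L,
            all(vapply(matrices, inherits, logical(1), "contact_matrix")))
  n_orig <- vapply(matrices, function(m) length(m$retained_mask), integer(1))
  res <- vapply(matrices, function(m) m$resolution, numeric(1))
  if (length(unique(n_orig)) != 1L || length(unique(res)) != 1L) {
    stop("matrices must share resolution and original bin count", call. = FALSE)
  }
  keep <- rep(TRUE, n_orig[[1L]])
  for (m in matrices) {
    ok <- rep(FALSE, n_orig[[1L]])
    ok[m$bins$index + 1L] <- !empty_bin_rows(m$values)
    keep <- keep & ok
  }
  if (!any(keep)) stop("empty intersection: no bin is non-empty in every matrix", call. = FALSE)
  lapply(matrices, function(m) {
    sel <- keep[m$bins$index + 1L]
    contact_matrix(m$values[sel, sel, drop = FALSE], m$resolution,
                   chrom = m$chrom, bins = m$bins[sel, , drop = FALSE],
                   retained_mask = keep, sample_id = m$sample_id,
                   balanced = m$balanced)
  })
}
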