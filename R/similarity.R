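#' Similarity score Q between two entropy signals
#'
#' The similarity score `Q` of two contact matrices is the Pearson
#' correlation coefficient between their entropy signals. The signals must be
#' comparable: same length and same resolved window geometry (`n`,
#' `phi_eff`), which in practice means they were computed on matrices
#' restricted to common non-empty bins (see [contact_similarity()]).
#'
#' @param sa,sb [entropy_signal()] objects.
#' @return `Q` in `[-1, 1]`.
#' @export
similarity_q <- function(sa, sb) {
  stopifnot(inherits(sa, "entropy_signal"), inherits(sb, "entropy_signal"))
  if (length(sa$values) != length(sb$values)) {
    stop("signals not comparable: lengths ", length(sa$values), " and ",
         length(sb$values), call. = FALSE)
  }
  if (sa$params$n != sb$params$n || sa$params$phi_eff != sb$params$phi_eff) {
    stop("signals not comparable: different window geometry", call. = FALSE)
  }
  if (stats::sd(sa$values) == 0 || stats::sd(sb$values) == 0) {
    stop("degenerate signal: zero variance", call. = FALSE)
  }
  stats::cor(sa$values, sb$values)
}

#' Similarity between two contact matrices
#'
#' End-to-end comparison on one chromosome: bins empty in either matrix are
#' excluded from both, the submatrix dimension is resolved once from the
#' common effective dimension (so both signals share the same geometry), both
#' entropy signals are computed, and `Q` is their Pearson correlation.
#'
#' @param ma,mb [contact_matrix()] objects on the same chromosome, resolution
#'   and original binning.
#' @param params An [ent3c_params()] object.
#' @return A list with elements `q`, `signal_a`, `signal_b`, `n_eff`.
#' @export
contact_similarity <- function(ma, mb, params = ent3c_params()) {
  common <- intersect_nonempty(list(ma, mb))
  n_eff <- nrow(common[[1L]]$values)
  resolved <- resolve_params(params, n_eff)
  fixed <- ent3c_params(c = params$c, n = resolved$n, phi = params$phi,
                        phi_max = params$phi_max)
  sa <- entropy_signal(common[[1L]], fixed)
  sb <- entropy_signal(common[[2L]], fixed)
  list(q = similarity_q(sa, sb), signal_a = sa, signal_b = sb, n_eff = n_eff)
}

#' Pairwise similarity table for a set of matrices
#'
#' Computes `Q` for every unordered pair of matrices on one chromosome.
#'
#' @param matrices Named list of [contact_matrix()] objects (names are sample
#'   ids; unnamed lists use each matrix's own `sample_id`).
#' @param params An [ent3c_params()] object.
#' @return A tibble with columns `sample_a`, `sample_b`, `chrom`, `q`.
#' @export
similarity_table <- function(matrices, params = ent3c_params()) {
  stopifnot(is.list(matrices), length(matrices) >= 2L)
  ids <- names(matrices)
  if (is.null(ids)) ids <- vapply(matrices, function(m) m$sample_id, character(1))
  pairs <- utils::combn(length(matrices), 2L)
  purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    cs <- contact_similarity(matrices[[i]], matrices[[j]], params)
    tibble::tibble(sample_a = ids[i], sample_b = ids[j],
                   chrom = matrices[[i]]$chrom, q = cs$q)
  })
}
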