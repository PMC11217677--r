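#' Log-transform a contact matrix
#'
#' Takes the natural logarithm of each entry. Zero counts and missing entries
#' become `NA` (not `-Inf`), so that the per-window minimum used for
#' imputation stays finite.
#'
#' @param m A [contact_matrix()] or non-negative numeric matrix.
#' @return A numeric matrix with `NA` where the input was zero or missing.
#' @export
log_transform <- function(m) {
  vals <- if (inherits(m, "contact_matrix")) m$values else as.matrix(m)
  if (any(vals < 0, na.rm = TRUE)) stop("entries must be non-negative", call. = FALSE)
  out <- suppressWarnings(log(vals))
  out[!is.finite(out)] <- NA_real_
  out
}

#' Impute missing entries in a diagonal window
#'
#' Replaces every missing entry of a log-transformed submatrix with the
#' minimum finite entry of that submatrix.
#'
#' @param a Numeric matrix (one diagonal window of the log-transformed
#'   contact matrix).
#' @return `a` with no missing entries.
#' @export
impute_submatrix <- function(a) {
  miss <- is.na(a)
  if (!any(miss)) return(a)
  if (all(miss)) stop("window fully empty", call. = FALSE)
  a[miss] <- min(a, na.rm = TRUE)
  a
}

#' Row-wise Pearson correlation matrix
#'
#' Computes the Pearson correlation between every pair of rows of `a`. The
#' diagonal is set to 1 exactly; correlations involving a zero-variance row
#' are set to 0, keeping the matrix symmetric with unit trace after the
#' `1/n` scaling so it remains a valid density-matrix analogue.
#'
#' @param a Numeric matrix with no missing entries and at least 2 rows.
#' @return Symmetric correlation matrix with entries in `[-1, 1]`.
#' @export
pearson_matrix <- function(a) {
  a <- as.matrix(a)
  if (nrow(a) < 2L) stop("need at least 2 rows for a correlation matrix", call. = FALSE)
  if (anyNA(a)) stop("matrix has missing entries; impute first", call. = FALSE)
  zv <- apply(a, 1L, stats::sd) == 0
  P <- suppressWarnings(stats::cor(t(a)))
  if (any(zv)) {
    P[zv, ] <- 0
    P[, zv] <- 0
  }
  P[is.na(P)] <- 0
  P <- pmin(pmax(P, -1), 1)
  diag(P) <- 1
  P
}

#' Von Neumann entropy of a correlation matrix
#'
#' Scales a Pearson correlation matrix `P` by its dimension `n` to obtain the
#' density-matrix analogue `rho = P/n` (Hermitian, positive semi-definite,
#' unit trace), then returns `S = -sum(lambda * log(lambda))` over the
#' positive eigenvalues `lambda` of `rho`, in nats. Eigenvalues `<= 0`
#' (including numerical dust below 1e-12 in magnitude) are ignored. For a
#' valid correlation matrix the result lies in `[0, log(n)]`: `log(n)` for
#' the identity (maximally mixed), 0 for the rank-one all-ones matrix.
#'
#' @param P Symmetric correlation matrix.
#' @return Entropy in nats.
#' @examples
#' vn_entropy(diag(10))            # log(10)
#' vn_entropy(matrix(1, 10, 10))   # 0
#' @export
vn_entropy <- function(P) {
  P <- as.matrix(P)
  if (nrow(P) != ncol(P)) stop("correlation matrix must be square", call. = FALSE)
  if (max(abs(P - t(P))) > 1e-8) stop("correlation matrix must be symmetric", call. = FALSE)
  n <- nrow(P)
  lam <- eigen(P / n, symmetric = TRUE, only.values = TRUE)$values
  lam[abs(lam) < 1e-12] <- 0
  lam <- lam[lam > 0]
  -sum(lam * log(lam))
}

#' Entropy signal along the diagonal of a contact matrix
#'
#' Computes the entropy signal `S`: the matrix is log-transformed, `Phi`
#' submatrices of dimension `n x n` are extracted along the diagonal at
#' shifts of `phi_eff` bins, each window is imputed (missing entries replaced
#' by the window minimum), Pearson-transformed, scaled by `1/n`, and its von
#' Neumann entropy computed. Empty bins are excluded first, so windows are
#' anchored on retained-bin indices and each window's genomic span runs from
#' the start of its first retained bin to the end of its last.
#'
#' @param m A [contact_matrix()].
#' @param params An [ent3c_params()] object.
#' @return An `entropy_signal` object: entropy values, per-window genomic
#'   spans, resolved parameters and provenance. Use [generics::tidy()] for a
#'   tibble.
#' @examples
#' m <- sample_counts(expected_intensity(synthetic_spec(N = 200, depth = 1e5)))
#' s <- entropy_signal(m, ent3c_params(c = 4))
#' head(tidy(s))
#' @export
entropy_signal <- function(m, params = ent3c_params()) {
  stopifnot(inherits(m, "contact_matrix"))
  m <- exclude_empty_bins(m)
  N <- nrow(m$values)
  p <- resolve_params(params, N)
  L <- log_transform(m)
  values <- numeric(p$Phi)
  starts <- integer(p$Phi)
  for (i in seq_len(p$Phi)) {
    first <- (i - 1L) * p$phi_eff + 1L
    idx <- first:(first + p$n - 1L)
    a <- impute_submatrix(L[idx, idx, drop = FALSE])
    values[i] <- vn_entropy(pearson_matrix(a))
    starts[i] <- first
  }
  windows <- tibble::tibble(
    window_index = seq_len(p$Phi) - 1L,
    chrom = m$chrom,
    start = m$bins$start[starts],
    end = m$bins$end[starts + p$n - 1L])
  structure(list(values = values, windows = windows, params = p,
                 sample_id = m$sample_id, chrom = m$chrom,
                 resolution = m$resolution),
            class = "entropy_signal")
}

#' @export
print.entropy_signal <- function(x, ...) {
  cat(sprintf("<entropy_signal> %s %s: Phi = %d windows (n = %d, phi_eff = %d), S in [%.3f, %.3f] nats\n",
              x$sample_id, x$chrom, x$params$Phi, x$params$n, x$params$phi_eff,
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
length.entropy_signal <- function(x) length(x$values)

#' Write an entropy signal as TSV
#'
#' One row per window with BED-compatible coordinate columns:
#' `sample_id, chrom, window_index, start, end, n, phi, S`.
#'
#' @param s An [entropy_signal()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signal <- function(s, path) {
  stopifnot(inherits(s, "entropy_signal"))
  utils::write.table(tidy(s), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
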