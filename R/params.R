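#' Analysis parameters for diagonal entropy signals
#'
#' Bundles the parameters controlling the sliding-window geometry of the
#' entropy signal: the chromosome split `c`, the submatrix dimension `n`
#' (derived from `c` when not given), the window shift `phi`, and the maximum
#' number of signal points `phi_max`.
#'
#' @param c Chromosome split: the matrix diagonal is partitioned into
#'   approximately `c` submatrices, giving `n = floor(N/c + 0.5)` for an
#'   effective matrix dimension `N`. Ignored when `n` is supplied. Default 7.
#' @param n Submatrix dimension. When given it takes precedence over `c`.
#'   Values below 50 give poorly sampled correlation matrices and trigger a
#'   warning at resolution time.
#' @param phi Window shift in bins between consecutive submatrices. Default 1.
#' @param phi_max Maximum number of points in the entropy signal. When the
#'   requested shift would produce more windows, the shift is enlarged
#'   minimally (see [effective_shift()]). Use `Inf` for no cap. Default 1000.
#' @return An object of class `ent3c_params`.
#' @examples
#' ent3c_params()                 # defaults: c = 7, phi = 1, phi_max = 1000
#' ent3c_params(n = 300, phi = 10, phi_max = Inf)
#' @export
ent3c_params <- function(c = 7L, n = NULL, phi = 1L, phi_max = 1000L) {
  if (!is.null(n)) {
    n <- as.integer(n)
    if (n < 2L) stop("submatrix dimension n must be at least 2", call. = FALSE)
  }
  c <- as.integer(c)
  if (is.na(c) || c < 1L) stop("chromosome split c must be a positive integer", call. = FALSE)
  phi <- as.integer(phi)
  if (is.na(phi) || phi < 1L) stop("window shift phi must be a positive integer", call. = FALSE)
  if (!is.infinite(phi_max)) {
    phi_max <- as.integer(phi_max)
    if (is.na(phi_max) || phi_max < 1L) stop("phi_max must be a positive integer or Inf", call. = FALSE)
  }
  structure(list(c = c, n = n, phi = phi, phi_max = phi_max),
            class = "ent3c_params")
}

#' @export
print.ent3c_params <- function(x, ...) {
  cat("<ent3c_params> c =", x$c,
      "| n =", if (is.null(x$n)) sprintf("(derived: floor(N/%d + 0.5))", x$c) else x$n,
      "| phi =", x$phi,
      "| phi_max =", if (is.infinite(x$phi_max)) "Inf" else x$phi_max, "\n")
  invisible(x)
}

#' Submatrix dimension from the chromosome split
#'
#' Computes the submatrix dimension as `n = floor(N/c + 0.5)` (round half up),
#' where `N` is the effective matrix dimension after empty-bin exclusion.
#'
#' @param N Effective matrix dimension (positive integer, `N >= c`).
#' @param c Chromosome split (positive integer).
#' @return Integer submatrix dimension.
#' @examples
#' choose_submatrix_dim(1751, 7)  # 250
#' @export
choose_submatrix_dim <- function(N, c) {
  stopifnot(length(N) == 1L, length(c) == 1L)
  if (c < 1) stop("chromosome split c must be >= 1", call. = FALSE)
  if (N < c) stop("matrix dimension N must be >= chromosome split c", call. = FALSE)
  n <- as.integer(floor(N / c + 0.5))
  if (n < 2L) stop("chromosome too small for split", call. = FALSE)
  n
}

#' Number of windows along the diagonal
#'
#' The entropy signal of an `N x N` matrix analysed with submatrix dimension
#' `n` and shift `phi` has `Phi = 1 + floor((N - n)/phi)` points.
#'
#' @param N Effective matrix dimension.
#' @param n Submatrix dimension, `n <= N`.
#' @param phi Window shift, `phi >= 1`.
#' @return Integer window count.
#' @examples
#' count_windows(1751, 300, 10)  # 146
#' count_windows(1751, 1743, 1)  # 9
#' @export
count_windows <- function(N, n, phi) {
  stopifnot(phi >= 1, n >= 1)
  if (N < n) stop("submatrix larger than matrix", call. = FALSE)
  as.integer(1L + floor((N - n) / phi))
}

#' Effective window shift under the signal-length cap
#'
#' When `count_windows(N, n, phi)` exceeds `phi_max`, the shift is enlarged to
#' the smallest value that respects the cap, `ceiling((N - n)/(phi_max - 1))`,
#' so that windows still cover the whole diagonal evenly instead of truncating
#' the distal chromosome arm.
#'
#' @inheritParams count_windows
#' @param phi_max Maximum number of signal points, or `Inf` for no cap.
#' @return Integer effective shift `>= phi`.
#' @examples
#' effective_shift(1751, 250, 1, 1000)  # 2 (751 windows)
#' @export
effective_shift <- function(N, n, phi, phi_max = Inf) {
  if (!is.infinite(phi_max) && phi_max < 1) stop("phi_max must be >= 1", call. = FALSE)
  if (N < n) stop("submatrix larger than matrix", call. = FALSE)
  if (is.infinite(phi_max) || count_windows(N, n, phi) <= phi_max) {
    return(as.integer(phi))
  }
  if (phi_max == 1) {
    # only the first window survives; any shift beyond the diagonal works
    return(as.integer(N - n + 1L))
  }
  phi_eff <- as.integer(ceiling((N - n) / (phi_max - 1)))
  max(as.integer(phi), phi_eff)
}

#' Resolve window geometry for a given matrix dimension
#'
#' Applies the precedence rule (`n` wins over `c`), the half-up rounding of
#' `n`, the shift cap, and the window-count formula, returning the final
#' geometry used to compute a signal.
#'
#' @param params An [ent3c_params()] object.
#' @param N Effective matrix dimension (after empty-bin exclusion).
#' @return A list with elements `n`, `phi` (requested), `phi_eff`, `Phi`, `c`.
#' @export
resolve_params <- function(params, N) {
  stopifnot(inherits(params, "ent3c_params"))
  n <- if (is.null(params$n)) choose_submatrix_dim(N, params$c) else params$n
  if (n > N) stop("submatrix larger than matrix", call. = FALSE)
  if (n < 50L) {
    warning("submatrix dimension n = ", n,
            " is below 50; entropy values may be poorly sampled", call. = FALSE)
  }
  phi_eff <- effective_shift(N, n, params$phi, params$phi_max)
  list(n = as.integer(n), phi = params$phi, phi_eff = phi_eff,
       Phi = count_windows(N, n, phi_eff), c = params$c)
}

#' Default chromosome split by binning resolution
#'
#' Returns the chromosome split `c` conventionally paired with a binning
#' resolution so the signal keeps enough points: 150 at 5 kb, 100 at 10 kb,
#' 25 at 25 kb, 7 at 40-50 kb, 6 at 100 kb, 3 at 500 kb and 2 at 1 Mb.
#' Unlisted resolutions fall back to the nearest tabulated one.
#'
#' @param resolution Binning resolution in bp.
#' @return Integer chromosome split.
#' @examples
#' default_split(40000)  # 7
#' @export
default_split <- function(resolution) {
  stopifnot(is.numeric(resolution), length(resolution) == 1L, resolution > 0)
  res <- c(5e3, 1e4, 2.5e4, 4e4, 5e4, 1e5, 5e5, 1e6)
  cc  <- c(150L, 100L, 25L, 7L, 7L, 6L, 3L, 2L)
  cc[which.min(abs(log(res) - log(resolution)))]
}
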