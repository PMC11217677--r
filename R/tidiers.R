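#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an entropy signal into a tibble
#'
#' One row per diagonal window: `sample_id`, `chrom`, `window_index`,
#' `start`, `end`, `n`, `phi`, `S`.
#'
#' @param x An [entropy_signal()].
#' @param ... Unused.
#' @method tidy entropy_signal
#' @export
tidy.entropy_signal <- function(x, ...) {
  tibble::tibble(sample_id = x$sample_id,
                 chrom = x$windows$chrom,
                 window_index = x$windows$window_index,
                 start = x$windows$start,
                 end = x$windows$end,
                 n = x$params$n,
                 phi = x$params$phi_eff,
                 S = x$values)
}

#' One-row summary of an entropy signal
#' @param x An [entropy_signal()].
#' @param ... Unused.
#' @method glance entropy_signal
#' @export
glance.entropy_signal <- function(x, ...) {
  tibble::tibble(sample_id = x$sample_id, chrom = x$chrom,
                 n = x$params$n, phi_eff = x$params$phi_eff,
                 Phi = x$params$Phi,
                 s_min = min(x$values), s_max = max(x$values),
                 s_mean = mean(x$values))
}

#' Per-cell-line benchmark statistics
#'
#' Returns one row per cell line with `q_br` (mean replicate similarity) and
#' the separating margin `d`, plus the cross-line `q_nr` rows.
#'
#' @param x An [aggregate_benchmark()] result.
#' @param ... Unused.
#' @method tidy ent3c_benchmark
#' @export
tidy.ent3c_benchmark <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(dplyr::select(x$br, cell_line = "cell_line", q = "q_br",
                                d = "d"),
                  relationship = "BR", .before = 1L),
    dplyr::mutate(dplyr::select(x$nr, cell_line = "line_a", other = "line_b",
                                q = "q_nr"),
                  relationship = "NR", .before = 1L))
}

#' Global benchmark means
#'
#' One row with `q_br_bar`, `q_nr_bar` and the average separating margin
#' `d_bar`.
#'
#' @param x An [aggregate_benchmark()] result.
#' @param ... Unused.
#' @method glance ent3c_benchmark
#' @export
glance.ent3c_benchmark <- function(x, ...) {
  tibble::tibble(q_br_bar = x$q_br_bar, q_nr_bar = x$q_nr_bar,
                 d_bar = x$d_bar)
}

#' Per-sample principal-component coordinates
#' @param x A [signal_pca()] result.
#' @param ... Unused.
#' @method tidy signal_pca
#' @export
tidy.signal_pca <- function(x, ...) x$scores

#' Variance explained per principal component
#' @param x A [signal_pca()] result.
#' @param ... Unused.
#' @method glance signal_pca
#' @export
glance.signal_pca <- function(x, ...) {
  tidyr::pivot_wider(x$variance, names_from = "component",
                     values_from = "variance_fraction")
}
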