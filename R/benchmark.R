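#' Aggregate pairwise similarity scores into benchmark statistics
#'
#' Given per-chromosome `Q` scores for all sample pairs and a sample sheet
#' assigning samples to cell lines, computes the replicate-benchmark summary:
#' for each cell line `i`, `Q_BR_i` is `Q` averaged first across chromosomes
#' within each biological-replicate pair, then across pairs; for each
#' unordered pair of cell lines `(i, j)`, `Q_NR_ij` averages likewise over
#' every cross-line replicate combination. The separating margin is
#' `d_i = Q_BR_i - median_j(Q_NR_ij)` over all lines `j != i`, and the global
#' means `Q_BR_bar`, `Q_NR_bar` and `d_bar` average over lines (respectively
#' unordered line pairs).
#'
#' @param qtable Tibble with columns `sample_a`, `sample_b`, `chrom`, `q`
#'   (from [similarity_table()], possibly row-bound across chromosomes).
#' @param sheet Tibble with columns `sample_id`, `cell_line` (and optionally
#'   `replicate`) mapping samples to cell lines.
#' @return An `ent3c_benchmark` object; see [tidy.ent3c_benchmark()] and
#'   [glance.ent3c_benchmark()].
#' @export
aggregate_benchmark <- function(qtable, sheet) {
  stopifnot(all(c("sample_a", "sample_b", "q") %in% names(qtable)),
            all(c("sample_id", "cell_line") %in% names(sheet)))
  unknown <- setdiff(unique(c(qtable$sample_a, qtable$sample_b)), sheet$sample_id)
  if (length(unknown)) {
    stop("samples missing from sheet: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  line_of <- stats::setNames(sheet$cell_line, sheet$sample_id)

  # chromosome-first averaging: one Q per sample pair
  pair_q <- qtable |>
    dplyr::group_by(.data$sample_a, .data$sample_b) |>
    dplyr::summarise(q = mean(.data$q), .groups = "drop") |>
    dplyr::mutate(line_a = unname(line_of[.data$sample_a]),
                  line_b = unname(line_of[.data$sample_b]))

  br <- pair_q |>
    dplyr::filter(.data$line_a == .data$line_b,
                  .data$sample_a != .data$sample_b) |>
    dplyr::group_by(cell_line = .data$line_a) |>
    dplyr::summarise(q_br = mean(.data$q), n_pairs = dplyr::n(),
                     .groups = "drop")

  singletons <- setdiff(unique(sheet$cell_line), br$cell_line)
  if (length(singletons)) {
    warning("cell line(s) with a single replicate contribute no Q_BR: ",
            paste(singletons, collapse = ", "), call. = FALSE)
  }

  nr <- pair_q |>
    dplyr::filter(.data$line_a != .data$line_b) |>
    dplyr::mutate(li = pmin(.data$line_a, .data$line_b),
                  lj = pmax(.data$line_a, .data$line_b)) |>
    dplyr::group_by(line_a = .data$li, line_b = .data$lj) |>
    dplyr::summarise(q_nr = mean(.data$q), n_pairs = dplyr::n(),
                     .groups = "drop")

  d_vals <- purrr::map2_dbl(br$cell_line, br$q_br, function(cl, qb) {
    others <- nr$q_nr[nr$line_a == cl | nr$line_b == cl]
    if (length(others)) qb - stats::median(others) else NA_real_
  })
  margin <- dplyr::mutate(br, d = d_vals)

  structure(list(
    pair_q = pair_q,
    br = margin,
    nr = nr,
    q_br_bar = if (nrow(br)) mean(br$q_br) else NA_real_,
    q_nr_bar = if (nrow(nr)) mean(nr$q_nr) else NA_real_,
    d_bar = if (any(!is.na(margin$d))) mean(margin$d, na.rm = TRUE) else NA_real_
  ), class = "ent3c_benchmark")
}

#' @export
print.ent3c_benchmark <- function(x, ...) {
  cat(sprintf("<ent3c_benchmark> Q_BR_bar = %.3f | Q_NR_bar = %.3f | d_bar = %.3f\n",
              x$q_br_bar, x$q_nr_bar, x$d_bar))
  cat(" per cell line:\n")
  print(x$br, ...)
  invisible(x)
}
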