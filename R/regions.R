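#' Highest- and lowest-complexity windows of an entropy signal
#'
#' Returns the `k` windows with the lowest and the `k` windows with the
#' highest entropy values, with their genomic spans. High entropy marks
#' intricate local contact patterns (complex 3D organization); low entropy
#' marks uniform ones. Ties are broken towards the lower window index.
#'
#' @param s An [entropy_signal()].
#' @param k Number of windows per extreme (default 1).
#' @return A tibble of region calls: `chrom`, `start`, `end`, `window_index`,
#'   `s_value`, `label` (`"min"` or `"max"`). Carries the theoretical entropy
#'   ceiling `log(n)` as attribute `s_max` for BED score scaling.
#' @export
extreme_windows <- function(s, k = 1L) {
  stopifnot(inherits(s, "entropy_signal"), k >= 1L, k <= length(s$values))
  v <- s$values
  lo <- order(v, seq_along(v))[seq_len(k)]
  hi <- order(-v, seq_along(v))[seq_len(k)]
  pick <- function(idx, label) {
    dplyr::mutate(s$windows[idx, , drop = FALSE],
                  s_value = v[idx], label = label)
  }
  out <- dplyr::bind_rows(pick(lo, "min"), pick(hi, "max")) |>
    dplyr::select("chrom", "start", "end", "window_index", "s_value", "label")
  attr(out, "s_max") <- log(s$params$n)
  out
}

#' Most similar regions between two entropy signals
#'
#' Fits an ordinary least-squares line of `sb` on `sa` and selects the
#' windows closest to the fit: the `ceiling(q * Phi)` windows with the
#' smallest absolute residuals (ties broken by window index). With the
#' default `q = 0.003` this reproduces the "below the 0.3% residual
#' quantile" selection rule.
#'
#' @param sa,sb Comparable [entropy_signal()] objects (same geometry).
#' @param q Residual quantile in (0, 1); default 0.003.
#' @return A tibble of region calls with `s_a`, `s_b`, `residual` and
#'   `label = "similar"`.
#' @export
similar_regions <- function(sa, sb, q = 0.003) {
  stopifnot(inherits(sa, "entropy_signal"), inherits(sb, "entropy_signal"))
  if (q <= 0 || q >= 1) stop("q must be in (0, 1)", call. = FALSE)
  if (length(sa$values) != length(sb$values) ||
      sa$params$n != sb$params$n || sa$params$phi_eff != sb$params$phi_eff) {
    stop("signals not comparable: different window geometry", call. = FALSE)
  }
  fit <- stats::lm(sb$values ~ sa$values)
  res <- abs(unname(stats::residuals(fit)))
  # exact fits leave float dust; zap it so ties break by index, not noise
  res[res <= 1e-10 * max(abs(sb$values), 1)] <- 0
  k <- min(ceiling(q * length(res)), length(res))
  sel <- order(res, seq_along(res))[seq_len(k)]
  sel <- sort(sel)
  out <- dplyr::mutate(sa$windows[sel, , drop = FALSE],
                       s_a = sa$values[sel], s_b = sb$values[sel],
                       residual = res[sel], label = "similar")
  attr(out, "s_max") <- log(sa$params$n)
  out
}

#' Principal component analysis of entropy signals
#'
#' Mean-centres a samples-by-windows matrix of entropy signals and computes
#' its principal components; replicate samples of the same cell line cluster
#' together, different cell lines separate (typically along PC1).
#'
#' @param signals A named list of comparable [entropy_signal()] objects, or a
#'   numeric matrix with one row per sample (rownames are sample ids).
#' @return A `signal_pca` object with `scores` (tibble: `sample_id`, `PC1`,
#'   `PC2`, ...) and `variance` (tibble: `component`, `variance_fraction`).
#' @export
signal_pca <- function(signals) {
  if (is.list(signals) && !is.matrix(signals)) {
    stopifnot(length(signals) >= 2L,
              all(vapply(signals, inherits, logical(1), "entropy_signal")))
    lens <- vapply(signals, function(s) length(s$values), integer(1))
    if (length(unique(lens)) != 1L) {
      stop("signals have different lengths; compute them on common bins",
           call. = FALSE)
    }
    ids <- names(signals)
    if (is.null(ids)) ids <- vapply(signals, function(s) s$sample_id, character(1))
    x <- do.call(rbind, lapply(signals, function(s) s$values))
    rownames(x) <- ids
  } else {
    x <- as.matrix(signals)
    if (nrow(x) < 2L) stop("need at least 2 samples", call. = FALSE)
    if (is.null(rownames(x))) rownames(x) <- paste0("sample_", seq_len(nrow(x)))
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  total <- sum(pc$sdev^2)
  frac <- if (total > 0) pc$sdev^2 / total else rep(0, length(pc$sdev))
  scores <- tibble::as_tibble(pc$x, .name_repair = "minimal")
  scores <- dplyr::bind_cols(tibble::tibble(sample_id = rownames(x)), scores)
  structure(list(
    scores = scores,
    variance = tibble::tibble(component = colnames(pc$x),
                              variance_fraction = frac),
    prcomp = pc
  ), class = "signal_pca")
}

#' @export
print.signal_pca <- function(x, ...) {
  v <- x$variance$variance_fraction
  cat(sprintf("<signal_pca> %d samples; PC1 %.1f%%, PC2 %.1f%% variance\n",
              nrow(x$scores), 100 * v[1L],
              if (length(v) > 1L) 100 * v[2L] else 0))
  print(x$scores, ...)
  invisible(x)
}

#' Write region calls as a BED file
#'
#' Writes `chrom start end name score` lines, `name = label:window_index` and
#' `score` the entropy value scaled linearly from `[0, log(n)]` to
#' `[0, 1000]`.
#'
#' @param calls A tibble from [extreme_windows()] or [similar_regions()].
#' @param path Output path.
#' @param s_max Entropy value mapping to score 1000; defaults to the `s_max`
#'   attribute attached by the callers.
#' @return `path`, invisibly.
#' @export
write_bed <- function(calls, path, s_max = attr(calls, "s_max")) {
  stopifnot(all(c("chrom", "start", "end", "window_index", "label") %in% names(calls)))
  if (is.null(s_max)) stop("s_max not supplied and not attached to calls", call. = FALSE)
  s <- if ("s_value" %in% names(calls)) calls$s_value else calls$s_a
  bed <- data.frame(chrom = calls$chrom,
                    start = format(calls$start, scientific = FALSE, trim = TRUE),
                    end = format(calls$end, scientific = FALSE, trim = TRUE),
                    name = paste0(calls$label, ":", calls$window_index),
                    score = as.integer(round(pmin(pmax(s / s_max, 0), 1) * 1000)))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
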