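#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point labs
#'   theme_minimal
#' @export
ggplot2::autoplot

#' Plot an entropy signal along the chromosome
#'
#' Line plot of the entropy of each diagonal window against its genomic
#' start coordinate (Mb).
#'
#' @param object An [entropy_signal()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot entropy_signal
#' @export
autoplot.entropy_signal <- function(object, ...) {
  d <- tidy(object)
  ggplot(d, aes(x = .data$start / 1e6, y = .data$S)) +
    geom_line(colour = "#2c5aa0") +
    labs(x = sprintf("%s position (Mb)", object$chrom),
         y = "von Neumann entropy S (nats)",
         title = object$sample_id,
         subtitle = sprintf("n = %d, phi = %d, Phi = %d",
                            object$params$n, object$params$phi_eff,
                            object$params$Phi)) +
    theme_minimal()
}

#' Plot samples in entropy-signal principal-component space
#'
#' @param object A [signal_pca()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot signal_pca
#' @export
autoplot.signal_pca <- function(object, ...) {
  v <- object$variance$variance_fraction
  ggplot(object$scores, aes(x = .data$PC1, y = .data$PC2,
                            label = .data$sample_id)) +
    geom_point(size = 2, colour = "#2c5aa0") +
    ggplot2::geom_text(vjust = -0.8, size = 3) +
    labs(x = sprintf("PC1 (%.1f%%)", 100 * v[1L]),
         y = sprintf("PC2 (%.1f%%)", 100 * v[2L])) +
    theme_minimal()
}

#' Dot plot of replicate vs non-replicate similarity scores
#'
#' For each cell line, plots its replicate score `Q_BR` and its scores
#' against every other line `Q_NR` — the at-a-glance view of the separating
#' margin.
#'
#' @param object An [aggregate_benchmark()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ent3c_benchmark
#' @export
autoplot.ent3c_benchmark <- function(object, ...) {
  d <- tidy(object)
  d$cell_line <- factor(d$cell_line)
  ggplot(d, aes(x = .data$q, y = .data$cell_line,
                colour = .data$relationship)) +
    geom_point(size = 2.5) +
    ggplot2::scale_colour_manual(values = c(BR = "#2c5aa0", NR = "#c0392b")) +
    ggplot2::xlim(-1, 1) +
    labs(x = "similarity score Q", y = NULL, colour = NULL,
         subtitle = sprintf("Q_BR_bar = %.2f, Q_NR_bar = %.2f, d_bar = %.2f",
                            object$q_br_bar, object$q_nr_bar, object$d_bar)) +
    theme_minimal()
}
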