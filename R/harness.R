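#' Replicate vs non-replicate benchmark on synthetic matrices
#'
#' The self-contained analogue of a replicate-reproducibility benchmark:
#' draws `n_pairs` randomly structured synthetic chromosomes, and for each
#' computes `Q` for a biological-replicate pair (two depth-limited samplings
#' of the same architecture) and, under matched sampling seeds, a
#' non-replicate pair (second matrix from a redrawn architecture). A useful
#' similarity score separates the two: `mean(Q_BR)` well above `mean(Q_NR)`.
#'
#' @param n_pairs Number of matched BR/NR pair draws (default 5).
#' @param N Bins per synthetic chromosome (default 1000).
#' @param depth Contacts per matrix (default 5e5).
#' @param seed Base seed; all structure and sampling seeds derive from it.
#' @param params [ent3c_params()] used for every comparison (defaults:
#'   `c = 7`, `phi = 1`, `phi_max = 1000`).
#' @param ... Passed to [random_synthetic_spec()] (e.g. `empty_fraction`).
#' @return A tibble with columns `pair`, `relationship` (`BR`/`NR`) and `q`.
#' @export
synthetic_benchmark <- function(n_pairs = 5L, N = 1000L, depth = 5e5,
                                seed = 1L, params = ent3c_params(), ...) {
  purrr::map_dfr(seq_len(n_pairs), function(i) {
    spec <- random_synthetic_spec(N = N, depth = depth,
                                  seed = seed + 100L * i, ...)
    seeds <- c(seed + 100L * i + 1L, seed + 100L * i + 2L)
    purrr::map_dfr(c("BR", "NR"), function(rel) {
      pr <- make_pair(spec, rel, seed_a = seeds[1L], seed_b = seeds[2L])
      tibble::tibble(pair = i, relationship = rel,
                     q = contact_similarity(pr$a, pr$b, params)$q)
    })
  })
}

#' Similarity stability across sequencing depths
#'
#' Computes the replicate similarity `Q_BR` of one synthetic architecture
#' sampled at several sequencing depths. A depth-robust score varies little
#' across orders of magnitude of depth.
#'
#' @param depths Vector of total contact counts (default
#'   `c(5e4, 5e5, 5e6)`).
#' @param N Bins (default 1000).
#' @param seed Base seed.
#' @param params [ent3c_params()] for every comparison.
#' @param ... Passed to [random_synthetic_spec()].
#' @return A tibble with columns `depth` and `q`.
#' @export
depth_robustness <- function(depths = c(5e4, 5e5, 5e6), N = 1000L, seed = 1L,
                             params = ent3c_params(), ...) {
  spec0 <- random_synthetic_spec(N = N, seed = seed, ...)
  purrr::map_dfr(depths, function(d) {
    spec <- spec0
    spec$depth <- d
    pr <- make_pair(spec, "BR", seed_a = seed + 11L, seed_b = seed + 12L)
    tibble::tibble(depth = d, q = contact_similarity(pr$a, pr$b, params)$q)
  })
}
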