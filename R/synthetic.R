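#' Specification of a synthetic intrachromosomal contact matrix
#'
#' Collects the generative parameters of a simulated Hi-C/micro-C matrix:
#' power-law distance decay, TAD block enrichment, A/B-compartment
#' checkerboard, total sequencing depth and forced-empty (unmappable) bins.
#' The expected intensity at bins `k`, `l` is
#' `mu_kl = (1 + |k - l|)^(-alpha) * T_kl * exp(cs * v_k * v_l)`,
#' where `T_kl = tad_strength` when `k` and `l` fall in the same TAD block
#' (else 1), `v` is the compartment profile and `cs` the compartment
#' strength.
#'
#' @param N Number of bins.
#' @param resolution Binning resolution in bp (default 40000, a typical
#'   working resolution for replicate comparison).
#' @param alpha Distance-decay exponent (> 0); contact frequency falls off as
#'   distance^(-alpha). Default 1, the classical fractal-globule regime.
#' @param tad_boundaries Sorted 0-based bin indices delimiting TAD blocks
#'   (boundaries at `0` and `N` are implicit).
#' @param tad_strength Multiplicative within-TAD enrichment (>= 1). Default 1
#'   (no block structure); [random_synthetic_spec()] uses 3.
#' @param compartment_profile Numeric vector of length `N` (signed amplitude
#'   per bin); default all zero (no compartments).
#' @param compartment_strength Non-negative scaling of the checkerboard term.
#' @param depth Total contact count to sample (default 5e5).
#' @param empty_fraction Fraction of bins forced empty (default 0).
#' @param empty_bins Explicit 0-based indices of forced-empty bins; overrides
#'   `empty_fraction`.
#' @param seed Seed controlling empty-bin placement and the default sampling
#'   seed.
#' @param sample_id Sample identifier.
#' @return A `synthetic_spec` object.
#' @export
synthetic_spec <- function(N = 1000L, resolution = 40000, alpha = 1,
                           tad_boundaries = integer(0), tad_strength = 1,
                           compartment_profile = NULL,
                           compartment_strength = 0,
                           depth = 5e5, empty_fraction = 0,
                           empty_bins = NULL, seed = 1L,
                           sample_id = "synthetic") {
  N <- as.integer(N)
  stopifnot(N >= 2L, alpha > 0, tad_strength >= 1, compartment_strength >= 0,
            depth >= 0, empty_fraction >= 0, empty_fraction < 1)
  if (is.null(compartment_profile)) compartment_profile <- numeric(N)
  stopifnot(length(compartment_profile) == N)
  tad_boundaries <- sort(unique(as.integer(tad_boundaries)))
  if (length(tad_boundaries) &&
      (min(tad_boundaries) < 0L || max(tad_boundaries) > N)) {
    stop("tad_boundaries must lie in [0, N]", call. = FALSE)
  }
  if (!is.null(empty_bins)) {
    empty_bins <- sort(unique(as.integer(empty_bins)))
    stopifnot(all(empty_bins >= 0L), all(empty_bins < N))
  }
  structure(list(N = N, resolution = resolution, alpha = alpha,
                 tad_boundaries = tad_boundaries, tad_strength = tad_strength,
                 compartment_profile = compartment_profile,
                 compartment_strength = compartment_strength,
                 depth = depth, empty_fraction = empty_fraction,
                 empty_bins = empty_bins, seed = as.integer(seed),
                 sample_id = sample_id),
            class = "synthetic_spec")
}

draw_structure <- function(N, tad_mean_size, comp_mean_size, seed) {
  withr::with_seed(seed, {
    sizes <- pmax(3L, stats::rpois(ceiling(2 * N / tad_mean_size), tad_mean_size))
    tad_boundaries <- cumsum(sizes)
    tad_boundaries <- tad_boundaries[tad_boundaries < N]
    blocks <- pmax(5L, stats::rpois(ceiling(2 * N / comp_mean_size), comp_mean_size))
    edges <- c(0L, cumsum(blocks))
    sign0 <- sample(c(-1, 1), 1L)
    profile <- numeric(N)
    for (b in seq_len(length(edges) - 1L)) {
      lo <- edges[b] + 1L
      if (lo > N) break
      hi <- min(edges[b + 1L], N)
      profile[lo:hi] <- sign0 * (-1)^(b - 1L)
    }
    list(tad_boundaries = tad_boundaries, compartment_profile = profile)
  })
}

#' Randomly structured synthetic spec
#'
#' Draws TAD boundaries (mean block size `tad_mean_size` bins) and an
#' alternating compartment profile (mean block size `comp_mean_size` bins)
#' from `seed`, then builds a [synthetic_spec()]. Two different seeds give
#' genuinely different architectures — the generator's model of two different
#' cell lines.
#'
#' @inheritParams synthetic_spec
#' @param tad_mean_size Mean TAD size in bins (default 12, i.e. ~500 kb at
#'   40 kb resolution).
#' @param comp_mean_size Mean compartment block size in bins (default 25,
#'   i.e. ~1 Mb at 40 kb resolution).
#' @param ... Passed to [synthetic_spec()].
#' @return A `synthetic_spec`.
#' @export
random_synthetic_spec <- function(N = 1000L, seed = 1L, tad_mean_size = 12,
                                  comp_mean_size = 25, tad_strength = 3,
                                  compartment_strength = 0.4,
                                  empty_fraction = 0.02, ...) {
  st <- draw_structure(N, tad_mean_size, comp_mean_size, seed)
  synthetic_spec(N = N, tad_boundaries = st$tad_boundaries,
                 tad_strength = tad_strength,
                 compartment_profile = st$compartment_profile,
                 compartment_strength = compartment_strength,
                 empty_fraction = empty_fraction, seed = seed, ...)
}

#' Expected intensity matrix of a synthetic spec
#'
#' Builds the noiseless ground-truth intensity `mu` (see [synthetic_spec()]
#' for the formula) and fixes the forced-empty bin indices.
#'
#' @param spec A [synthetic_spec()].
#' @return A `ground_truth` object: `mu` (symmetric positive matrix), `spec`,
#'   and `empty_bins` (0-based indices).
#' @export
expected_intensity <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  N <- spec$N
  d <- abs(outer(seq_len(N), seq_len(N), "-"))
  mu <- (1 + d)^(-spec$alpha)
  if (spec$tad_strength > 1) {
    block <- findInterval(seq_len(N) - 1L, spec$tad_boundaries)
    same <- outer(block, block, "==")
    mu[same] <- mu[same] * spec$tad_strength
  }
  if (spec$compartment_strength > 0) {
    v <- spec$compartment_profile
    mu <- mu * exp(spec$compartment_strength * outer(v, v))
  }
  empty_bins <- spec$empty_bins
  if (is.null(empty_bins)) {
    n_empty <- round(spec$empty_fraction * N)
    empty_bins <- if (n_empty > 0) {
      withr::with_seed(spec$seed + 777L,
                       sort(sample.int(N, n_empty)) - 1L)
    } else integer(0)
  }
  structure(list(mu = mu, spec = spec, empty_bins = empty_bins),
            class = "ground_truth")
}

#' Sample a contact matrix at finite sequencing depth
#'
#' Draws `depth` contacts from the upper triangle (diagonal included) of the
#' ground-truth intensity with multinomial probabilities proportional to
#' `mu`, symmetrizes, then zeroes the forced-empty bins. The total count
#' equals `depth` exactly before empty-bin zeroing.
#'
#' @param gt A [expected_intensity()] ground truth.
#' @param depth Total contact count (default from the spec).
#' @param seed RNG seed (default from the spec).
#' @param sample_id Sample identifier (default from the spec).
#' @return A [contact_matrix()] of raw counts (all bins retained; forced-empty
#'   bins are all-zero rows until [exclude_empty_bins()]).
#' @export
sample_counts <- function(gt, depth = gt$spec$depth, seed = gt$spec$seed,
                          sample_id = gt$spec$sample_id) {
  stopifnot(inherits(gt, "ground_truth"), depth >= 0)
  N <- nrow(gt$mu)
  ut <- upper.tri(gt$mu, diag = TRUE)
  p <- gt$mu[ut]
  counts <- matrix(0, N, N)
  if (depth > 0) {
    draw <- withr::with_seed(seed,
                             stats::rmultinom(1L, size = depth, prob = p)[, 1L])
    counts[ut] <- draw
    counts <- counts + t(counts) - diag(diag(counts))
  }
  if (length(gt$empty_bins)) {
    idx <- gt$empty_bins + 1L
    counts[idx, ] <- 0
    counts[, idx] <- 0
  }
  contact_matrix(counts, gt$spec$resolution, sample_id = sample_id)
}

#' Binomial thinning of a count matrix
#'
#' Downsamples a raw-count contact matrix to approximately `m` total contacts
#' by independent binomial thinning of each upper-triangle cell with ratio
#' `m/total` — the matrix-level analogue of subsampling a pairs file.
#'
#' @param M A [contact_matrix()] of integer counts.
#' @param m Target total count (`<=` current total).
#' @param seed RNG seed.
#' @return A thinned [contact_matrix()].
#' @export
downsample <- function(M, m, seed = 1L) {
  stopifnot(inherits(M, "contact_matrix"))
  vals <- M$values
  if (any(is.na(vals)) || any(vals != round(vals))) {
    stop("downsampling requires integer raw counts", call. = FALSE)
  }
  ut <- upper.tri(vals, diag = TRUE)
  total <- sum(vals[ut])
  if (m > total) stop("target exceeds total count (", total, ")", call. = FALSE)
  ratio <- if (total > 0) m / total else 0
  out <- matrix(0, nrow(vals), ncol(vals))
  if (ratio == 1) {
    out <- vals
  } else if (ratio > 0) {
    thinned <- withr::with_seed(seed,
                                stats::rbinom(sum(ut), size = as.integer(vals[ut]),
                                              prob = ratio))
    out[ut] <- thinned
    out <- out + t(out) - diag(diag(out))
  }
  contact_matrix(out, M$resolution, chrom = M$chrom, bins = M$bins,
                 retained_mask = M$retained_mask,
                 sample_id = paste0(M$sample_id, "_ds"), balanced = FALSE)
}

#' Generate a replicate or non-replicate matrix pair
#'
#' `BR` (biological replicate) pairs are two independent count samplings from
#' the same ground-truth intensity; `NR` (non-replicate) pairs redraw the TAD
#' boundaries and compartment profile for the second matrix under the same
#' hyperparameters — different architecture, as between cell lines.
#'
#' @param spec A [synthetic_spec()] (for NR redraws, one produced by
#'   [random_synthetic_spec()]).
#' @param relationship `"BR"` or `"NR"`.
#' @param seed_a,seed_b Sampling seeds for the two matrices. For NR pairs,
#'   `seed_b` also seeds the redrawn architecture.
#' @param tad_mean_size,comp_mean_size Structure hyperparameters used for the
#'   NR redraw (defaults as in [random_synthetic_spec()]).
#' @return A list with matrices `a`, `b` and ground truths `gt_a`, `gt_b`.
#' @export
make_pair <- function(spec, relationship = c("BR", "NR"),
                      seed_a = spec$seed + 1L, seed_b = spec$seed + 2L,
                      tad_mean_size = 12, comp_mean_size = 25) {
  relationship <- match.arg(relationship)
  stopifnot(inherits(spec, "synthetic_spec"))
  gt_a <- expected_intensity(spec)
  gt_b <- if (relationship == "BR") {
    gt_a
  } else {
    st <- draw_structure(spec$N, tad_mean_size, comp_mean_size,
                         seed = seed_b + 10000L)
    spec_b <- synthetic_spec(N = spec$N, resolution = spec$resolution,
                             alpha = spec$alpha,
                             tad_boundaries = st$tad_boundaries,
                             tad_strength = spec$tad_strength,
                             compartment_profile = st$compartment_profile,
                             compartment_strength = spec$compartment_strength,
                             depth = spec$depth,
                             empty_fraction = spec$empty_fraction,
                             empty_bins = spec$empty_bins,
                             seed = seed_b,
                             sample_id = paste0(spec$sample_id, "_alt"))
    expected_intensity(spec_b)
  }
  a <- sample_counts(gt_a, seed = seed_a,
                     sample_id = paste0(spec$sample_id, "_a"))
  b <- sample_counts(gt_b, seed = seed_b,
                     sample_id = paste0(gt_b$spec$sample_id, "_b"))
  list(a = a, b = b, gt_a = gt_a, gt_b = gt_b, relationship = relationship)
}
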