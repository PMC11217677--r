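---
title: "Entropy signals and contact-matrix similarity: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Entropy signals and contact-matrix similarity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hicentropy)
```

## The model

An intrachromosomal contact matrix **A** = (A~kl~) is an N×N symmetric,
non-negative matrix whose entries estimate 3D interaction frequencies
between genomic bins of fixed width (the binning resolution, in bp).
`hicentropy` summarises the local pattern complexity of **A** as an
*entropy signal* and scores two matrices by the correlation of their
signals.

The construction, per diagonal window:

1. **Empty-bin exclusion.** A bin is empty when its whole row is zero (raw
   counts) or missing (balanced values with undefined weights). Empty bins
   are removed before anything else; all window arithmetic runs on the
   effective dimension N (retained bins). Windows are anchored on
   retained-bin indices, and each window's genomic span runs from the start
   of its first retained bin to the end of its last, so spans remain honest
   BED intervals even across excluded gaps.
2. **Log transform.** Contact counts are heavy-tailed with a power-law
   distance decay; the natural logarithm puts rows on a scale where Pearson
   correlation is meaningful. Zeros and missing values become `NA` at this
   stage rather than −∞, so they cannot poison the next step.
3. **Windowing and imputation.** Φ = 1 + ⌊(N−n)/φ⌋ windows of size n×n are
   slid along the diagonal at shift φ. Within each window, `NA` entries are
   replaced by the window's minimum finite entry — a conservative "below
   detection" value local to the window.
4. **Pearson transform and entropy.** The window's rows are correlated
   pairwise to give **P**; then ρ = **P**/n is Hermitian, positive
   semi-definite with unit trace, and its von Neumann entropy
   S(ρ) = −Σ~λ>0~ λ ln λ (eigenvalues of ρ) is reported in nats. S ranges
   from 0 (rank-one ρ: all rows perfectly correlated, a featureless window)
   to ln n (ρ ∝ I: maximally mixed, rich uncorrelated structure).

The similarity of two matrices is **Q**, the Pearson correlation of their
entropy signals. Before computing signals for a comparison, bins empty in
*either* matrix are excluded from *both*, and the submatrix dimension is
resolved once from the common effective dimension — otherwise the two
signals would have incompatible window geometries.

## Parameters

| parameter | meaning | default | rationale |
|---|---|---|---|
| `c` | chromosome split; sets n = ⌊N/c + 0.5⌋ | 7 | ~7 windows spanning a human chromosome at 40–50 kb keeps n in the hundreds |
| `n` | window dimension (bins) | derived from `c` | explicit `n` wins over `c`; values < 50 warn — the correlation matrix of so few rows is poorly sampled |
| `phi` | window shift (bins) | 1 | densest signal; shifts approaching n skip diagonal segments entirely and degrade Q |
| `phi_max` | cap on signal length Φ | 1000 | bounds the O(Φ·n³) eigen-decomposition cost |

`default_split()` maps resolution to the conventional split (150 at 5 kb,
100 at 10 kb, 25 at 25 kb, 7 at 40–50 kb, 6 at 100 kb, 3 at 500 kb, 2 at
1 Mb), keeping Φ usefully large at every resolution.

When Φ at the requested shift exceeds `phi_max`, the shift is enlarged to
the smallest compliant value, φ′ = ⌈(N−n)/(Φ_max−1)⌉, rather than
truncating the signal at Φ_max windows: truncation would silently drop the
distal chromosome arm from every comparison. With `phi_max = 1` a single
window anchored at the matrix start is returned. The rounding in
n = ⌊N/c + 0.5⌋ is literal round-half-up (floor of N/c + 0.5), not banker's
rounding.

## Numerical choices

* **Log base.** Natural log throughout; entropies are in nats and bounded
  by ln n. Q is invariant to the base (a global rescaling of both signals
  cancels in the correlation), so this is purely a reporting convention.
* **Sign convention.** S = −Σ λ ln λ, the non-negative von Neumann form. A
  global sign flip would cancel in Q; the non-negative convention keeps the
  [0, ln n] interpretation.
* **Zero-variance rows.** After imputation a window row can be constant
  (e.g. a window that is entirely imputed minimum). Correlations involving
  such rows are set to 0 and the diagonal to 1, which keeps **P** symmetric
  with unit trace after scaling — ρ stays a valid density-matrix analogue.
  A fully constant window therefore scores S = ln n (maximal mixing): the
  convention is mechanical, not a biological statement.
* **Eigenvalues.** λ ≤ 0 are ignored (they are numerical artifacts:
  ρ is PSD in exact arithmetic); additionally |λ| < 1e−12 is clipped to 0
  before the positivity test so log is never taken of rounding dust. The
  eigenvalue sum of each analysed window equals 1 within 1e−8 (tested).
* **Comparable signals.** `similarity_q()` refuses signals of different
  length or window geometry, and zero-variance (degenerate) signals, rather
  than returning a misleading number.
* **Residual ties.** `similar_regions()` ranks windows by absolute OLS
  residual and returns the ⌈q·Φ⌉ smallest (ties broken by window index).
  A literal quantile threshold is ill-defined at its own boundary cases: in
  a perfect affine fit all residuals are zero and a "strictly below the
  quantile" rule would select nothing while "at or below" would select
  everything. Rank selection gives a deterministic set of the intended
  size, is monotone in q, and residual float dust below
  1e−10·max|S~b~| is zapped so exact fits tie-break by position rather
  than rounding noise.

## Design choices where the design was open

* **Balancing.** Both raw and balanced matrices are accepted
  (`load_cooler(balanced = TRUE)` applies the stored per-bin weights as
  w~k~·A~kl~·w~l~; undefined weights poison their bin). Raw counts are the
  default everywhere, and balancing is never computed — only consumed.
* **Fit direction.** `similar_regions()` regresses the second signal on the
  first (S~b~ ~ S~a~). OLS is not symmetric in its arguments; the choice is
  fixed and documented rather than hidden.
* **Aggregation order.** Benchmark summaries average Q across chromosomes
  within a sample pair first, then across replicate pairs, then across cell
  lines; non-replicate statistics use unordered cell-line pairs counted
  once. The separating margin d~i~ subtracts the *median* of a line's
  cross-line scores, making it robust to one aberrant partner line.
* **Multi-sample geometry.** For PCA across many samples, all matrices are
  restricted to their common non-empty bins and one n is resolved from the
  common dimension, so every signal lives on the same windows.

## The synthetic generator

`synthetic_spec()` builds a ground-truth intensity

μ~kl~ = (1 + |k−l|)^−α^ · T~kl~ · exp(c~s~·v~k~·v~l~),

with decay exponent α (default 1, the classical fractal-globule regime),
T~kl~ = `tad_strength` within a TAD block (default 3 in
`random_synthetic_spec()`, a typical fold-enrichment for domain interiors),
and a ±1 compartment profile v scaled by `compartment_strength` (default
0.4, i.e. ~2.2-fold checkerboard contrast between same- and cross-
compartment contacts). Sequencing depth is emulated by a single multinomial
draw of `depth` contacts over the upper triangle (total depth is exact;
pairs-file subsampling is emulated separately by binomial thinning in
`downsample()`), and a fraction of bins (default 2%, matching typical
unmappable fractions at 40 kb) is forced empty. Structure draws use mean
TAD size 12 bins (~500 kb at 40 kb) and mean compartment block 25 bins
(~1 Mb). All outputs are pure functions of the spec and seeds.

Biological-replicate (BR) pairs are two independent samplings of one μ;
non-replicate (NR) pairs redraw TAD boundaries and compartment profile for
the second matrix — different architecture, as between cell lines.

**What the generator does not emulate.** Bins are statistically
exchangeable apart from architecture: there is no per-bin coverage bias
(GC content, mappability, fragment density), no karyotype, no balancing-
weight structure, and no long-range noise correlation. This matters for
interpreting the tests: real replicates share bin-level biases, which keep
their entropy signals correlated even at extreme sparsity, while synthetic
replicates share only architecture. Consequently, on 1000-bin synthetic
chromosomes the replicate score Q_BR is high and stable at 5×10⁵–5×10⁶
contacts (~500–5000 per bin-row) but can collapse at 5×10⁴ (~50 per
bin-row), where independent sampling noise dominates the signal; the
acceptance script reports the measured range across those three depths.
Passing synthetic tests therefore demonstrates the score's architecture
sensitivity and its noise robustness at moderate depth, not its behaviour
on heavily downsampled real libraries.

## Problem sizes used in the test suite

The suite exercises full-size window geometry arithmetic symbolically
(e.g. N = 1751, n = 300, φ = 10 ⇒ Φ = 146) and runs end-to-end pipelines on
matrices of 60–1000 bins: 1000-bin chromosomes at depth 5×10⁵ for the BR/NR
separation and empty-bin contracts (five matched pair draws), 200–300 bins
for signal properties, and 5×5 random correlation matrices against a
matrix-logarithm oracle for the entropy kernel. These sizes give stable
statistics for the properties under test while the whole suite completes in
a few minutes.

## Known limitations

* Only intrachromosomal (cis) matrices; no trans contacts, and no entropy
  bands away from the main diagonal.
* Matrix balancing is consumed, never computed.
* Q needs enough signal points: tiny chromosomes or extreme n leave too few
  windows for a meaningful correlation (the n < 50 warning, and the
  degenerate-signal error, guard the worst cases).
* The similar-regions selection stops at BED output of genomic spans; gene
  annotation and enrichment are out of scope.
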