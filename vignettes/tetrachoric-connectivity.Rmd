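---
title: "Tetrachoric correlation for voxel-level connectivity graphs: model, design and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tetrachoric correlation for voxel-level connectivity graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcgraph)
```

## The model

A voxel-level functional connectivity graph takes individual voxels as
nodes and establishes edges from the pairwise linear correlation of their
time series. The conventional estimator is Pearson's sample correlation r
on the continuous series. This package additionally implements the
dichotomization route: each series is binarized at its own median
(values **at least** the median map to 1, so ties go to 1), and the latent
correlation of the pair is estimated by the tetrachoric coefficient,
which assumes the underlying pair is bivariate normal.

The tetrachoric estimator generally requires solving a bivariate-normal
orthant integral numerically. A median split is the special case in which
both marginal probabilities are fixed at 1/2; the 2×2 contingency table is
then fully determined by the joint frequency p11 = n11/T of time points
where both binary series are 1, and the integral collapses to the closed
form

$$r_t = -\cos(2 \pi \, p_{11}).$$

This is why the package dichotomizes at the median and nowhere else: for
any other threshold the closed form is invalid, and supporting numerical
tetrachoric estimation is an explicit non-goal.

Two consequences shape the implementation:

* **n11 is a bit-counting problem.** After packing the binary series into
  machine words, n11 for a pair is the popcount of the bitwise AND of
  their words. With T scans this costs ⌈T/64⌉ word operations per pair
  instead of T multiply–adds.
* **r_t is discrete.** For tie-free median splits n11 can only attain
  0…T/2 (even T) or 1…(T+1)/2 (odd T), so r_t takes at most T/2 + 1
  distinct values. The builder therefore reads r_t from a lookup table
  indexed by n11 and never re-evaluates the cosine per pair; the discrete
  value set is also why joint histograms involving r_t show vertical gaps.

## Numerical and layout choices

**Bit order and word width.** Time point k maps to bit k mod w of word
⌊k/w⌋ (little-endian bit significance). Under this convention the
byte-level layout is identical for widths 8, 32 and 64, so the packed
buffer is stored as raw bytes padded with zeros to whole 64-bit blocks and
the requested width is kept as metadata; the kernels always operate on
64-bit loads. Padding bits are guaranteed zero, which makes popcounts over
whole words exact — this invariant is tested by masking.

**Lookup-table domain.** Although only 0…⌈T/2⌉ is attainable for tie-free
splits, the table covers 0…T so that heavily tied input can never index
out of range; counts above ⌈T/2⌉ trigger a warning instead of an error.
The closed form is evaluated as `-cos(2*pi*(n11/T))` — ratio first — in
both the table and the scalar function, so the two paths are bit-identical.

**Degenerate series.** A constant series has an undefined correlation
under both estimators (zero variance for r; an all-ones binary series with
no median split for r_t). Such rows are processed but flagged, and every
pair involving a flagged row is reported as missing rather than as a
fabricated value, keeping the two estimators' behaviour symmetric. Missing
pairs are never eligible for edges.

**Blocked Pearson baseline.** Per-voxel means and centered norms are
precomputed once; the pair loop then runs over square row blocks so each
block stays cache-resident. The block size is a memory-schedule knob with
no observable effect: the per-pair dot product always accumulates in time
order, so triangles are bit-identical across block sizes (the tests assert
identity, which is stronger than the 1e-6 contract). Computed correlations
are clamped to [−1, 1] to absorb last-bit rounding.

**Triangle storage.** Only the upper triangle (i &lt; j) is stored, in
row-major order; `tri_index()` is the 1-based bijection and is
exhaustively verified for V ≤ 30. Serialization is a flat little-endian
double array plus a JSON sidecar (V, T, estimator, layout, missing count).

## Graph construction

Densities, not thresholds, are comparable across subjects, so the package
fixes the density κ and derives the cutoff θ per matrix. The edge rule
"c &gt; θ" and "exact density" cannot both hold when ties straddle the
boundary, so the implementation selects the top round(κ·V(V−1)/2) pairs by
value with lexicographic (i, j) tie-breaking — deterministic and exactly
at target density (within the one-edge rounding) — and reports θ as the
midpoint between the smallest included and largest excluded value. For
tie-free boundaries, thresholding at θ reproduces the edge set exactly.

Degrees are z-scored with the population (n-denominator) standard
deviation; the standardization formula is a design choice here since only
"standardized" is conventionally specified, and z-scoring is the standard
reading. Group maps average per-subject standardized degree maps
voxel-wise on a pre-aligned shared grid, discarding voxels supported by
fewer than 20% of subjects (the default `support_fraction = 0.2`).
Spatial normalization across subjects is deliberately out of scope: group
averaging assumes the grids are already aligned, which the synthetic
fixtures guarantee by construction.

## The simulation study

`run_study()` draws, for every ρ in {−0.99, −0.98, …, 0.99} (199 values),
`n_reps` independent bivariate-normal samples of size T as
y = ρx + √(1−ρ²)z, computes r on the continuous pair and r_t after median
dichotomization of each margin, and tabulates per-bin mean, SD and mean
signed difference MSD(est, ρ) = mean(est) − ρ. Joint histograms use bins
centered on the grid values with half-open [low, high) edges at midpoints;
the outer bins absorb overflow to ±1, so counts are conserved exactly.
T = 100 and T = 300 are the study's reference sample sizes, bracketing
typical resting-state scan counts.

Because 199 × 10000 per-sample estimates are never needed simultaneously,
the study accumulates per-bin moments (sums, squares and cross-products)
and derives grid-wide correlations of (r, ρ), (r_t, ρ) and (r_t, r) and
the pooled Deming fit from those moments; the tests verify this
aggregation against a brute-force per-sample computation on a small grid.

The Deming regression uses error-variance ratio δ = 1 (orthogonal
regression): both estimators target the same ρ on the same scale, so
equal error variances are the natural default; δ is exposed as a
parameter. The bias of r is compared against the classical approximation
E(r) − ρ = −ρ(1−ρ²)/(2n); the empirical MSD(r, ρ) matches it within
Monte-Carlo error, while MSD(r_t, ρ) shows the same sign pattern with
larger amplitude — the quantified cost of discarding amplitude
information, alongside per-bin SDs roughly 1.5× those of r.

## Synthetic data: what it does and does not show

`make_timeseries()` plants disjoint clusters in which every member is
√ρ·shared + √(1−ρ)·idiosyncratic with standard-normal latents, giving an
expected within-cluster pairwise correlation of exactly ρ against a
background of independent noise voxels; `make_nifti_dataset()` embeds the
matrix in a 4D NIfTI volume with a gray-matter probability map that is
≥ 0.2 exactly at the planted voxels, so the mask reader recovers the
planted nodes at the default threshold. Defaults follow a
Pittsburgh-like acquisition (T = 275, TR = 1.5 s; the alternative
Cambridge-like setting is T = 119, TR = 3 s) with one 20-voxel cluster at
ρ = 0.7 — strong but realistic within-network coherence.

The end-to-end recovery check uses V = 200 voxels on a 10×10×10 grid: at
κ = 0.01 the graph admits 199 edges, the 190 within-cluster pairs dominate
the ranking for both estimators, and the cluster members are exactly the
top-degree nodes, with degree sequences from the r- and r_t-graphs
correlating above 0.9. This is the desk-scale stand-in for the real-data
degree concordance; real resting-state data differ in ways the generator
does not emulate (autocorrelated and non-Gaussian noise, heterogeneous
correlation structure, motion and physiological artifacts), so passing
these tests demonstrates correctness of the pipeline and the estimators'
agreement under bivariate normality, not robustness to every property of
empirical BOLD signals. Notably, a *single uniform-ρ* cluster leaves the
within-cluster edge ranking entirely to sampling noise, which lowers
between-estimator degree correlation at small V; the heterogeneous
structure of real data is what drives the very high concordances reported
in applications.

**Band-pass preprocessing** uses a zero-phase (forward–backward)
Butterworth design of order 4 per edge, with the customary resting-state
band 0.01–0.1 Hz; the filter type is a preprocessing choice upstream of
the method's contribution, and any standard zero-phase band-pass would
serve. Edges beyond Nyquist (1/(2·TR)) are rejected rather than silently
clamped.

## Problem sizes and tolerances

The shipped test suite runs the full 199-bin grid at n_reps = 2500,
scaling the reference tolerances (±0.005 on SDs, ±0.003 on grid-wide
correlations at n_reps = 10000) by √(10000/n_reps), the standard-error
scaling for Monte-Carlo checks; `scripts/acceptance.R` runs the full
10000-replicate studies. Oracle-equivalence tests use V ≤ 100 with
T ∈ {99, 100, 119, 275}, covering both parities and both acquisition-like
lengths. The Pearson-oracle tolerance of 1e-6 relative allows for
summation-order differences; in practice the builders agree bit-exactly.

## Known limitations

* The closed form is valid only for median splits; arbitrary-threshold
  tetrachoric estimation is not provided.
* Only binary graphs and the degree metric are implemented; weighted
  graphs and further graph metrics are out of scope.
* Group averaging requires pre-aligned grids; no spatial normalization,
  motion correction or segmentation is performed.
* Hardware-specific SIMD/popcount intrinsics and multi-threading are not
  used; performance claims are limited to the algorithmic reduction
  (⌈T/64⌉ word operations per pair, upper-triangle storage).
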