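# fcgraph

Fast construction of voxel-level functional connectivity graphs from
fMRI-like time series, using median dichotomization and tetrachoric
correlation as a drop-in alternative to Pearson's r.

## The problem and the method

Voxel-level functional connectivity analysis correlates the BOLD time
series of every pair of gray-matter voxels, thresholds the resulting
correlation matrix into a binary graph, and summarises the graph with
metrics such as node degree. At native resolution the pair count V(V−1)/2
runs into the billions, and the correlation matrix is by far the most
expensive step.

`fcgraph` implements the fast route: each voxel time series *s_v* is
dichotomized at its own median (*d_{v,k} = 1* iff *s_{v,k} ≥ median(s_v)*),
and the correlation of the latent continuous pair is estimated by the
tetrachoric coefficient. Because a median split fixes both marginals of the
2×2 contingency table at 1/2, the table is determined by the single joint
frequency *p11 = n11 / T*, and the usual bivariate-normal integral has the
closed form

    r_t = −cos(2π · p11),   n11 = Σ_k d_{v,k} · d_{w,k}.

The binary series are bit-packed into machine words, so *n11* for a pair is
obtained with bitwise AND plus popcount over ⌈T/64⌉ words, and *r_t* is read
from a precomputed lookup table over the attainable counts
(0…T/2 for even T, 1…(T+1)/2 for odd T). A blocked Pearson builder with
precomputed per-voxel means and norms provides the conventional baseline;
both builders store only the upper triangle. Graphs are formed by
density-based thresholding (a per-matrix cutoff θ chosen so that every
graph has the same density κ = 2|E|/(V(V−1))), degrees are z-scored per
subject, and per-subject degree maps can be averaged voxel-wise on a shared
grid with a minimum-support rule.

A bivariate-normal simulation study (`run_study()`) quantifies the price of
dichotomization: per-ρ-bin mean, SD and mean signed difference for both
estimators over ρ ∈ {−0.99, …, 0.99}, joint histograms, the closed-form
bias approximation E(r) − ρ = −ρ(1−ρ²)/(2n), and a Deming
(errors-in-variables) fit to the pooled (r_t, r) pairs.

## Worked example

Plant a 20-voxel cluster (within-correlation 0.7) among 200 voxels with
T = 275 scans, build both graphs at density κ = 0.01, and compare degrees:

```r
library(fcgraph)

spec <- planted_spec(V = 200, T = 275,
                     clusters = tibble::tibble(size = 20, rho = 0.7),
                     seed = 7)
gen <- make_timeseries(spec)

pb   <- pack_bits(dichotomize_matrix(gen$ts), word_width = 32)
C_rt <- cor_tetrachoric(pb)          # AND + popcount + lookup
C_r  <- cor_pearson(gen$ts)          # blocked continuous baseline

G_rt <- density_threshold(C_rt, kappa = 0.01)
G_r  <- density_threshold(C_r,  kappa = 0.01)
G_rt
#> <fc_graph> V = 200  |E| = 199  kappa = 0.01  theta = 0.3199
G_r
#> <fc_graph> V = 200  |E| = 199  kappa = 0.01  theta = 0.2109

cor(graph_degree(G_r), graph_degree(G_rt))
#> 0.997
```

Both estimators select 199 edges (exactly κ = 0.01), the two degree
sequences agree at r = 0.997, and the 20 top-degree nodes are exactly the
planted cluster — the dichotomized route recovers the same hubs as the
continuous one. The θ values differ because r_t and r place the same
density cutoff at different points of their value ranges.

The simulation study reports how the estimators behave against known ρ:

```r
st <- run_study(T = 100, n_reps = 2000, seed = 11, keep_histograms = FALSE)
st
#> <fc_sim_study> T = 100  n_reps = 2000  bins = 199
#>   SD at rho=0: r=0.0979  r_t=0.1522
#>   grid-wide correlations: r_rho=0.9918  rt_rho=0.9778  rt_r=0.9858
```

SD(r_t) exceeds SD(r) in every bin (the cost of discarding amplitude
information), both estimators track ρ nearly linearly, and the Deming slope
of (r_t, r) sits at ≈ 1. `tidy()`/`glance()` return these results as
tibbles; `autoplot(st, type = "summary" | "bias" | "histogram")` draws the
standard composite figures.

NIfTI volumes enter through `load_dataset(functional, gm_map, theta_gm =
0.2)` (nodes = supra-threshold gray-matter voxels) after optional
`bandpass(ts, TR, 0.01, 0.1)` filtering; `write_value_map()` puts node
statistics back into volume space. A command-line wrapper with
`synth`/`corr`/`graph`/`degree`/`group`/`sim` subcommands is installed at
`system.file("cli", "fcgraph.R", package = "fcgraph")`.

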