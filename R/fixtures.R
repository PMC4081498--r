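#' Specification for synthetic voxel time series with planted clusters
#'
#' Describes a V x T synthetic data set emulating preprocessed resting-state
#' voxel time series: a set of disjoint clusters whose members share a latent
#' signal (so every within-cluster pair has a known expected correlation),
#' embedded in independent noise voxels. Defaults mirror a
#' Pittsburgh-like acquisition (T = 275 scans, TR = 1.5 s) with one cluster
#' of 20 voxels at within-correlation 0.7 among 100 voxels.
#'
#' @param V Number of voxels.
#' @param T Number of scans.
#' @param clusters Data frame / tibble with columns `size` and `rho`
#'   (within-cluster pairwise correlation, in (0, 1)); sizes must sum to at
#'   most V. May have zero rows.
#' @param TR Repetition time in seconds (metadata; used by [bandpass()] and
#'   NIfTI export).
#' @param seed Optional integer seed.
#' @return A `planted_spec` list.
#' @export
planted_spec <- function(V = 100L, T = 275L,
                         clusters = tibble::tibble(size = 20L, rho = 0.7),
                         TR = 1.5, seed = NULL) {
  clusters <- tibble::as_tibble(clusters)
  stopifnot(V >= 2, T >= 2, TR > 0)
  if (nrow(clusters)) {
    stopifnot(all(c("size", "rho") %in% names(clusters)))
    if (any(clusters$rho <= 0 | clusters$rho >= 1)) {
      stop("within-cluster correlations must lie in (0, 1)")
    }
    if (sum(clusters$size) > V) stop("cluster sizes exceed V")
  }
  structure(list(V = as.integer(V), T = as.integer(T), clusters = clusters,
                 TR = TR, seed = seed),
            class = "planted_spec")
}

#' Generate a planted-structure time-series matrix
#'
#' Cluster members are built as sqrt(rho) * shared + sqrt(1 - rho) *
#' idiosyncratic with all latents standard normal, so each within-cluster
#' pair has expected correlation exactly rho; remaining voxels are
#' independent standard-normal noise. Cluster members occupy the leading
#' rows, in cluster order.
#'
#' @param spec A `planted_spec`.
#' @return List with `ts` (V x T matrix), `membership` (integer vector,
#'   0 = background noise, c = cluster c), and `spec`.
#' @export
make_timeseries <- function(spec) {
  stopifnot(inherits(spec, "planted_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  V <- spec$V; T <- spec$T
  ts <- matrix(stats::rnorm(V * T), V, T)
  membership <- integer(V)
  row <- 1L
  for (c in seq_len(nrow(spec$clusters))) {
    size <- spec$clusters$size[c]
    rho <- spec$clusters$rho[c]
    shared <- stats::rnorm(T)
    idx <- row:(row + size - 1L)
    ts[idx, ] <- sqrt(rho) * matrix(shared, size, T, byrow = TRUE) +
      sqrt(1 - rho) * ts[idx, , drop = FALSE]
    membership[idx] <- c
    row <- row + size
  }
  list(ts = ts, membership = membership, spec = spec)
}

#' Write a synthetic NIfTI data set with a gray-matter probability map
#'
#' Embeds the planted time series of [make_timeseries()] into a 4D volume on
#' the given grid and writes a matching 3D gray-matter probability map:
#' exactly the V planted voxels receive GM probability >= 0.2 (drawn in
#' [0.2, 1]), all others < 0.2, so [load_dataset()] at the default threshold
#' recovers exactly the planted nodes in grid order. Ground truth
#' (membership, coordinates) goes to a JSON sidecar.
#'
#' @param spec A `planted_spec`.
#' @param grid_shape 3D grid dimensions, prod >= V.
#' @param dir Output directory (created if needed).
#' @return List with paths `functional`, `gm_map`, `truth`, plus the
#'   generated `ts` and `membership`.
#' @export
make_nifti_dataset <- function(spec, grid_shape = c(10L, 10L, 10L),
                               dir = tempfile("fcgraph_synth_")) {
  stopifnot(inherits(spec, "planted_spec"), length(grid_shape) == 3L)
  if (prod(grid_shape) < spec$V) stop("grid too small for V voxels")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gen <- make_timeseries(spec)
  V <- spec$V; T <- spec$T
  # planted voxels occupy the first V grid positions in linear order
  idx <- seq_len(V)
  gm <- array(stats::runif(prod(grid_shape), 0, 0.19), grid_shape)
  gm[idx] <- stats::runif(V, 0.2, 1)
  vol <- array(stats::rnorm(prod(grid_shape) * T, sd = 0.1),
               c(grid_shape, T))
  flat <- matrix(vol, prod(grid_shape), T)
  flat[idx, ] <- gen$ts
  vol <- array(flat, c(grid_shape, T))
  f_func <- file.path(dir, "functional.nii.gz")
  f_gm <- file.path(dir, "gm.nii.gz")
  f_truth <- file.path(dir, "truth.json")
  RNifti::writeNifti(RNifti::asNifti(vol, pixdim = c(3, 3, 3, spec$TR)),
                     f_func)
  RNifti::writeNifti(RNifti::asNifti(gm, pixdim = c(3, 3, 3)), f_gm)
  co <- arrayInd(idx, grid_shape)
  jsonlite::write_json(
    list(V = V, T = T, TR = spec$TR, theta_gm = 0.2,
         membership = gen$membership,
         coords = unname(as.data.frame(co))),
    f_truth, auto_unbox = TRUE, digits = NA)
  list(functional = f_func, gm_map = f_gm, truth = f_truth,
       ts = gen$ts, membership = gen$membership)
}
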