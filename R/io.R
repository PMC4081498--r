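#' Extract voxel time series from a 4D volume under a gray-matter mask
#'
#' Nodes are the voxels whose gray-matter probability is at least
#' `theta_gm`, taken in deterministic grid (column-major linear) order; one
#' time series per node is pulled from the 4D functional volume.
#'
#' @param functional Path to a 4D NIfTI volume (or an array).
#' @param gm_map Path to the matching 3D GM probability map (or an array).
#' @param theta_gm GM probability threshold; default 0.2.
#' @return List with `ts` (V x T matrix) and `mask` (a `voxel_mask`: grid
#'   `dim`, linear `idx`, `coords` V x 3 matrix, `theta_gm`).
#' @export
load_dataset <- function(functional, gm_map, theta_gm = 0.2) {
  vol <- if (is.character(functional)) {
    if (!file.exists(functional)) stop("functional volume not found: ",
                                       functional)
    as.array(RNifti::readNifti(functional))
  } else as.array(functional)
  gm <- if (is.character(gm_map)) {
    if (!file.exists(gm_map)) stop("GM map not found: ", gm_map)
    as.array(RNifti::readNifti(gm_map))
  } else as.array(gm_map)
  if (length(dim(vol)) != 4L) stop("functional volume must be 4D")
  if (length(dim(gm)) != 3L) stop("GM map must be 3D")
  if (!identical(dim(vol)[1:3], dim(gm))) {
    stop("functional and GM grids differ: ",
         paste(dim(vol)[1:3], collapse = "x"), " vs ",
         paste(dim(gm), collapse = "x"))
  }
  idx <- which(gm >= theta_gm)
  if (length(idx) == 0L) stop("no voxels at or above theta_gm = ", theta_gm)
  T <- dim(vol)[4L]
  ts <- matrix(vol, prod(dim(gm)), T)[idx, , drop = FALSE]
  mask <- structure(list(dim = dim(gm), idx = idx,
                         coords = arrayInd(idx, dim(gm)),
                         theta_gm = theta_gm),
                    class = "voxel_mask")
  list(ts = ts, mask = mask)
}

#' @export
print.voxel_mask <- function(x, ...) {
  cat("<voxel_mask>", paste(x$dim, collapse = "x"), "grid,",
      length(x$idx), "nodes at theta_gm =", x$theta_gm, "\n")
  invisible(x)
}

#' Zero-phase band-pass filter for voxel time series
#'
#' Removes slow intensity drifts and high-frequency noise with a zero-phase
#' (forward-backward) Butterworth band-pass, the customary resting-state
#' band being 0.01-0.1 Hz. DC (0 Hz) lies in the stop band and is removed.
#'
#' @param ts Numeric matrix (V x T, one series per row) or vector.
#' @param TR Repetition time in seconds (sampling interval).
#' @param low,high Pass-band edges in Hz; `0 <= low < high <= 1/(2 TR)`.
#' @param order Butterworth design order per edge; default 4.
#' @return Filtered series with unchanged dimensions.
#' @export
bandpass <- function(ts, TR, low = 0.01, high = 0.1, order = 4L) {
  stopifnot(TR > 0)
  nyquist <- 1 / (2 * TR)
  if (low < 0 || low >= high) stop("need 0 <= low < high")
  if (high > nyquist) {
    stop("high = ", high, " Hz exceeds the Nyquist frequency ",
         signif(nyquist, 4), " Hz at TR = ", TR, " s")
  }
  bf <- signal::butter(order, c(low, high) / nyquist, type = "pass")
  filt1 <- function(x) signal::filtfilt(bf, x - mean(x))
  if (is.matrix(ts)) {
    t(apply(ts, 1L, filt1))
  } else {
    filt1(ts)
  }
}

#' Write node values back into volume space as a 3D NIfTI map
#'
#' Places one value per node at its masked voxel coordinate; all other
#' voxels are NA. The inverse of the extraction step of [load_dataset()].
#'
#' @param values Numeric vector, one value per mask node.
#' @param mask A `voxel_mask`.
#' @param path Output NIfTI path (optional; if NULL the array is returned
#'   without writing).
#' @return The 3D array, invisibly if written.
#' @export
write_value_map <- function(values, mask, path = NULL) {
  stopifnot(inherits(mask, "voxel_mask"))
  if (length(values) != length(mask$idx)) {
    stop("need exactly one value per mask node")
  }
  arr <- array(NA_real_, mask$dim)
  arr[mask$idx] <- values
  if (is.null(path)) return(arr)
  RNifti::writeNifti(RNifti::asNifti(arr), path)
  invisible(arr)
}

#' Read / write a plain-text V x T time-series matrix
#'
#' Tab-delimited, no header: rows are voxels, columns scans; the headless
#' input format of the command-line interface.
#'
#' @param path File path.
#' @return `read_timeseries_tsv()`: numeric matrix.
#' @export
read_timeseries_tsv <- function(path) {
  if (!file.exists(path)) stop("time-series file not found: ", path)
  as.matrix(utils::read.table(path, sep = "\t"))
}

#' @rdname read_timeseries_tsv
#' @param ts Numeric matrix to write.
#' @export
write_timeseries_tsv <- function(ts, path) {
  utils::write.table(ts, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
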