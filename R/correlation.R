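#' Pearson correlation of a single pair of series
#'
#' Computes r as the ratio of the centered cross-product to the product of
#' centered norms. Returns `NA` (with a warning) if either series is
#' constant.
#'
#' @param s_v,s_w Numeric vectors of equal length >= 3.
#' @return Correlation in \[-1, 1\], or `NA_real_` for degenerate input.
#' @export
pearson_pair <- function(s_v, s_w) {
  stopifnot(is.numeric(s_v), is.numeric(s_w))
  if (length(s_v) != length(s_w)) stop("series lengths differ")
  if (length(s_v) < 3L) stop("need at least 3 time points")
  cv <- s_v - mean(s_v)
  cw <- s_w - mean(s_w)
  den <- sqrt(sum(cv^2) * sum(cw^2))
  if (den == 0) {
    warning("constant series: Pearson correlation undefined")
    return(NA_real_)
  }
  min(1, max(-1, sum(cv * cw) / den))
}

new_cor_triangle <- function(values, V, estimator, T = NA_integer_) {
  stopifnot(length(values) == V * (V - 1) / 2)
  structure(
    list(values = as.numeric(values), V = as.integer(V),
         estimator = estimator, T = as.integer(T),
         missing = is.na(values)),
    class = "cor_triangle"
  )
}

#' Linear position of a node pair in the upper-triangular layout
#'
#' The upper triangle (i < j) is stored row-major; this maps an unordered
#' node pair to its 1-based linear position. `tri_index(i, j, V)` equals
#' `tri_index(j, i, V)`; the diagonal is not stored.
#'
#' @param i,j Node indices (1-based), `i != j`, both <= `V`.
#' @param V Number of nodes.
#' @return Integer position in `1:(V*(V-1)/2)`. Vectorized over `i`, `j`.
#' @export
tri_index <- function(i, j, V) {
  if (any(i == j)) stop("no self-pairs: i must differ from j")
  if (any(i < 1L | j < 1L | i > V | j > V)) stop("node index out of range")
  lo <- pmin(i, j) - 1L   # 0-based
  hi <- pmax(i, j) - 1L
  as.integer(lo * V - lo * (lo + 1L) / 2 + (hi - lo - 1L) + 1L)
}

#' Symmetric lookup into a correlation triangle
#'
#' @param C A `cor_triangle`.
#' @param i,j Node indices (1-based).
#' @return Correlation value(s); `NA` for degenerate pairs.
#' @export
cor_entry <- function(C, i, j) {
  stopifnot(inherits(C, "cor_triangle"))
  C$values[tri_index(i, j, C$V)]
}

#' Blocked Pearson correlation triangle
#'
#' Computes all pairwise Pearson correlations of the rows of `ts`, storing
#' only the upper triangle (i < j, row-major). Per-voxel means and centered
#' norms are precomputed once; the pair loop is blocked so that each block of
#' centered rows stays cache-resident. The block size changes the memory
#' schedule only, never the result. Zero-variance rows yield missing entries.
#'
#' @param ts Numeric V x T matrix, one voxel time series per row.
#' @param block Block size (rows per block), default 64.
#' @return A `cor_triangle` with estimator `"r"`.
#' @export
cor_pearson <- function(ts, block = 64L) {
  stopifnot(is.matrix(ts), is.numeric(ts))
  if (nrow(ts) < 2L) stop("need at least two voxels (V >= 2)")
  if (ncol(ts) < 3L) stop("need at least 3 time points")
  vals <- cpp_pearson_tri(ts, as.integer(block))
  if (anyNA(vals)) warning("degenerate (constant) rows: entries set missing")
  new_cor_triangle(vals, nrow(ts), "r", ncol(ts))
}

#' Tetrachoric lookup table
#'
#' Precomputes rt = -cos(2*pi*n/T) for every joint-ones count n in 0..T.
#' Under tie-free median splits n11 can only attain 0..T/2 (even T) or
#' 1..(T+1)/2 (odd T); the attainable set is recorded in `attainable`. The
#' full 0..T domain is covered so tied data can never index out of range.
#'
#' @param T Series length (number of scans), >= 2.
#' @return List with `table` (numeric, length T+1, index n11 + 1),
#'   `attainable` (integer vector), and `T`.
#' @export
tetrachoric_lookup <- function(T) {
  stopifnot(T >= 2)
  T <- as.integer(T)
  attainable <- if (T %% 2L == 0L) 0L:(T %/% 2L) else 1L:((T + 1L) %/% 2L)
  list(table = -cos(2 * pi * ((0:T) / T)), attainable = attainable, T = T)
}

#' Tetrachoric correlation from a joint-ones count
#'
#' Closed form for median-dichotomized data: rt = -cos(2*pi*n11/T). With the
#' marginals fixed at 1/2 by the median split, the joint cell n11 determines
#' the whole 2x2 contingency table, and the usual bivariate-normal integral
#' collapses to this cosine. Counts above ceil(T/2) are impossible for
#' tie-free median splits; they are still evaluated but trigger a warning.
#'
#' @param n11 Joint-ones count(s), 0 <= n11 <= T.
#' @param T Series length.
#' @return rt value(s) in \[-1, 1\]. Vectorized over `n11`.
#' @export
tetrachoric_from_n11 <- function(n11, T) {
  stopifnot(T >= 2, all(n11 >= 0), all(n11 <= T))
  if (any(n11 > ceiling(T / 2))) {
    warning("n11 exceeds ceil(T/2): impossible under tie-free median splits ",
            "(tied or non-median-split input?)")
  }
  -cos(2 * pi * (n11 / T))  # p11 first: bit-identical to the lookup table
}

#' Tetrachoric correlation triangle from packed binary series
#'
#' For every pair i < j, applies bitwise AND to the packed series, popcounts
#' the result to obtain n11, and reads rt off the precomputed lookup table
#' (the cosine is never re-evaluated per pair). Pairs involving degenerate
#' (constant-source) series are reported missing.
#'
#' @param pb A `packed_bits` object from [pack_bits()].
#' @return A `cor_triangle` with estimator `"r_t"`; every non-missing value
#'   lies in the attainable set of [tetrachoric_lookup()].
#' @export
cor_tetrachoric <- function(pb) {
  stopifnot(inherits(pb, "packed_bits"))
  V <- attr(pb, "V"); T <- attr(pb, "T")
  if (V < 2L) stop("need at least two voxels (V >= 2)")
  lut <- tetrachoric_lookup(T)
  n11 <- cpp_n11_tri(unclass(pb), V, T)
  vals <- lut$table[n11 + 1L]
  degen <- attr(pb, "degenerate")
  if (any(degen)) {
    bad <- which(degen)
    i <- rep.int(seq_len(V - 1L), (V - 1L):1L)
    j <- sequence((V - 1L):1L) + i
    vals[i %in% bad | j %in% bad] <- NA_real_
  }
  new_cor_triangle(vals, V, "r_t", T)
}

#' @export
print.cor_triangle <- function(x, ...) {
  cat("<cor_triangle> estimator =", x$estimator, " V =", x$V,
      " pairs =", length(x$values), " missing =", sum(x$missing), "\n")
  invisible(x)
}

#' Dense symmetric matrix from a correlation triangle
#'
#' @param x A `cor_triangle`.
#' @param diag Value for the diagonal (default 1).
#' @param ... Unused.
#' @return V x V symmetric numeric matrix.
#' @export
as.matrix.cor_triangle <- function(x, diag = 1, ...) {
  V <- x$V
  m <- matrix(diag, V, V)
  ut <- upper.tri(m)
  m[ut] <- x$values[tri_index(row(m)[ut], col(m)[ut], V)]
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}

#' Tidy a correlation triangle into a pair table
#'
#' @param x A `cor_triangle`.
#' @param ... Unused.
#' @return Tibble with columns `i`, `j` (1-based, i < j) and `value`.
#' @export
as_tibble.cor_triangle <- function(x, ...) {
  V <- x$V
  i <- rep.int(seq_len(V - 1L), (V - 1L):1L)
  j <- sequence((V - 1L):1L) + i
  tibble::tibble(i = i, j = j, value = x$values)
}

#' Write / read a correlation triangle
#'
#' The triangle is serialized as a flat little-endian double array
#' (`<path>.bin`) plus a JSON sidecar (`<path>.json`) recording V, T,
#' estimator, layout and missing count. Missing entries are stored as NaN.
#'
#' @param C A `cor_triangle`.
#' @param path Output path prefix (no extension).
#' @return `write_triangle()`: `path`, invisibly. `read_triangle()`: the
#'   restored `cor_triangle`.
#' @export
write_triangle <- function(C, path) {
  stopifnot(inherits(C, "cor_triangle"))
  con <- file(paste0(path, ".bin"), "wb")
  on.exit(close(con))
  writeBin(ifelse(is.na(C$values), NaN, C$values), con,
           size = 8L, endian = "little")
  jsonlite::write_json(
    list(V = C$V, T = C$T, estimator = C$estimator,
         layout = "upper-triangular-row-major",
         n_pairs = length(C$values), n_missing = sum(C$missing)),
    paste0(path, ".json"), auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_triangle
#' @export
read_triangle <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  con <- file(paste0(path, ".bin"), "rb")
  on.exit(close(con))
  vals <- readBin(con, "double", n = meta$n_pairs, size = 8L,
                  endian = "little")
  vals[is.nan(vals)] <- NA_real_
  new_cor_triangle(vals, meta$V, meta$estimator, meta$T)
}
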