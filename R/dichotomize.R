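#' Median-dichotomize a time series
#'
#' Converts a continuous series into a binary one using its sample median as
#' the threshold: bit k is 1 iff `x[k] >= median(x)`. Ties at the median are
#' assigned 1, so for tie-free data the number of 1s is `T/2` (even `T`) or
#' `(T+1)/2` (odd `T`). A constant series dichotomizes to all 1s and is
#' flagged degenerate (attribute `"degenerate"`), since no correlation can be
#' estimated against it.
#'
#' @param x Numeric vector of length >= 2 with finite values.
#' @return Integer 0/1 vector of the same length, with attribute
#'   `degenerate` (logical scalar).
#' @examples
#' median_dichotomize(c(1, 2, 3, 4))
#' @export
median_dichotomize <- function(x) {
  stopifnot(is.numeric(x), length(x) >= 2)
  if (!all(is.finite(x))) stop("series contains non-finite values")
  med <- stats::median(x)
  bits <- as.integer(x >= med)
  degen <- all(x == x[1])
  if (degen) {
    warning("constant series: dichotomization is degenerate, ",
            "correlations against this node are undefined")
  }
  structure(bits, degenerate = degen)
}

#' Median-dichotomize every row of a time-series matrix
#'
#' @param ts Numeric matrix, one series per row (V x T).
#' @return Integer 0/1 matrix of the same shape, with attribute `degenerate`,
#'   a logical vector marking constant (zero-variance) rows.
#' @export
dichotomize_matrix <- function(ts) {
  stopifnot(is.matrix(ts), is.numeric(ts), ncol(ts) >= 2)
  if (!all(is.finite(ts))) stop("time series contain non-finite values")
  med <- cpp_col_medians(t(ts))
  bits <- matrix(as.integer(ts >= med), nrow(ts), ncol(ts))
  degen <- apply(ts, 1L, function(r) all(r == r[1]))
  if (any(degen)) {
    warning(sum(degen), " constant series flagged degenerate")
  }
  structure(bits, degenerate = degen)
}

#' Bit-pack binary time series
#'
#' Packs a V x T matrix of 0/1 values into machine words so that pairwise
#' joint-ones counts can be computed with bitwise AND plus popcount. Time
#' point k maps to bit `k %% word_width` of word `k %/% word_width`
#' (little-endian bit significance); with this convention the byte-level
#' layout is identical for all supported word widths, so the buffer is stored
#' as raw bytes padded with zeros to whole 64-bit blocks. Padding bits are
#' always zero, which makes popcounts over whole words exact.
#'
#' @param bits Integer/numeric/logical V x T matrix of 0/1 values, or the
#'   result of [dichotomize_matrix()] (its degenerate flags are carried over).
#' @param word_width Nominal word width in bits; one of 8, 32, 64. Metadata
#'   only under the little-endian convention.
#' @return A `packed_bits` object.
#' @seealso [unpack_bits()], [popcounts()], [cor_tetrachoric()]
#' @export
pack_bits <- function(bits, word_width = 32L) {
  stopifnot(is.matrix(bits))
  if (ncol(bits) < 1L) stop("empty series cannot be packed")
  if (!word_width %in% c(8L, 32L, 64L)) {
    stop("word_width must be one of 8, 32, 64")
  }
  degen <- attr(bits, "degenerate")
  storage.mode(bits) <- "integer"
  if (anyNA(bits) || !all(bits == 0L | bits == 1L)) {
    stop("bits must be 0 or 1")
  }
  if (is.null(degen)) degen <- rep(FALSE, nrow(bits))
  structure(
    cpp_pack_bits(bits),
    V = nrow(bits), T = ncol(bits),
    word_width = as.integer(word_width),
    bytes_per_series = 8L * ((ncol(bits) + 63L) %/% 64L),
    degenerate = degen,
    class = "packed_bits"
  )
}

#' Unpack a bit-packed binary matrix
#'
#' Exact inverse of [pack_bits()].
#'
#' @param pb A `packed_bits` object.
#' @return Integer 0/1 matrix (V x T).
#' @export
unpack_bits <- function(pb) {
  stopifnot(inherits(pb, "packed_bits"))
  cpp_unpack_bits(unclass(pb), attr(pb, "V"), attr(pb, "T"))
}

#' Per-series popcounts of a packed binary matrix
#'
#' @param pb A `packed_bits` object.
#' @return Integer vector of length V: the number of 1s in each series.
#' @export
popcounts <- function(pb) {
  stopifnot(inherits(pb, "packed_bits"))
  cpp_popcount_rows(unclass(pb), attr(pb, "V"), attr(pb, "T"))
}

#' Extract one packed series
#'
#' @param pb A `packed_bits` object.
#' @param v Series (node) index, 1-based.
#' @return Raw vector holding the padded words of series `v`, with attribute
#'   `T`.
#' @export
packed_series <- function(pb, v) {
  stopifnot(inherits(pb, "packed_bits"))
  V <- attr(pb, "V")
  if (v < 1L || v > V) stop("series index out of range")
  B <- attr(pb, "bytes_per_series")
  raw <- unclass(pb)[((v - 1L) * B + 1L):(v * B)]
  structure(raw, T = attr(pb, "T"))
}

#' Joint-ones count of two packed series
#'
#' Applies bitwise AND to the packed words and counts set bits, yielding
#' n11 = sum_k d_v[k] * d_w[k].
#'
#' @param p_v,p_w Packed series from [packed_series()] (or a whole
#'   `packed_bits` row pair via that helper).
#' @return Integer joint-ones count.
#' @export
n11_pair <- function(p_v, p_w) {
  if (!identical(attr(p_v, "T"), attr(p_w, "T"))) {
    stop("packed series have different lengths T")
  }
  cpp_n11_pair(as.raw(p_v), as.raw(p_w))
}

#' @export
print.packed_bits <- function(x, ...) {
  cat("<packed_bits> V =", attr(x, "V"), " T =", attr(x, "T"),
      " word_width =", attr(x, "word_width"),
      " degenerate =", sum(attr(x, "degenerate")), "\n")
  invisible(x)
}

#' @export
dim.packed_bits <- function(x) c(attr(x, "V"), attr(x, "T"))
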