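// Low-level kernels: bit packing, AND+popcount joint counts, blocked Pearson
// triangle, column medians. Packed layout: one series occupies
// bytes_per_series = 8*ceil(T/64) consecutive bytes; time point k lives in
// byte k>>3, bit k&7 (little-endian bit significance). Padding bits are zero,
// so popcounts over whole 64-bit words need no masking.

#include <Rcpp.h>
#include <cstdint>
#include <cstring>
#include <algorithm>
#include <vector>

using namespace Rcpp;

static inline int pop64(uint64_t x) {
#if defined(__GNUC__) || defined(__clang__)
  return __builtin_popcountll(x);
#else
  int n = 0;
  while (x) { x &= x - 1; ++n; }
  return n;
#endif
}

static inline R_xlen_t bytes_per_series(int T) {
  return 8 * ((static_cast<R_xlen_t>(T) + 63) / 64);
}

// [[Rcpp::export]]
RawVector cpp_pack_bits(const IntegerMatrix& bits) {
  const int V = bits.nrow(), T = bits.ncol();
  const R_xlen_t B = bytes_per_series(T);
  RawVector out(B * V);  // zero-initialised: padding bits are zero
  for (int v = 0; v < V; ++v) {
    Rbyte* row = &out[static_cast<R_xlen_t>(v) * B];
    for (int k = 0; k < T; ++k) {
      const int b = bits(v, k);
      if (b != 0 && b != 1) stop("bits must be 0 or 1");
      if (b) row[k >> 3] |= static_cast<Rbyte>(1u << (k & 7));
    }
  }
  return out;
}

// [[Rcpp::export]]
IntegerMatrix cpp_unpack_bits(const RawVector& packed, int V, int T) {
  const R_xlen_t B = bytes_per_series(T);
  if (static_cast<R_xlen_t>(packed.size()) != B * V)
    stop("packed buffer has unexpected size");
  IntegerMatrix out(V, T);
  for (int v = 0; v < V; ++v) {
    const Rbyte* row = &packed[static_cast<R_xlen_t>(v) * B];
    for (int k = 0; k < T; ++k)
      out(v, k) = (row[k >> 3] >> (k & 7)) & 1;
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_popcount_rows(const RawVector& packed, int V, int T) {
  const R_xlen_t B = bytes_per_series(T);
  const R_xlen_t W = B / 8;
  IntegerVector out(V);
  for (int v = 0; v < V; ++v) {
    const Rbyte* row = &packed[static_cast<R_xlen_t>(v) * B];
    int n = 0;
    uint64_t w;
    for (R_xlen_t j = 0; j < W; ++j) {
      std::memcpy(&w, row + 8 * j, 8);
      n += pop64(w);
    }
    out[v] = n;
  }
  return out;
}

// [[Rcpp::export]]
int cpp_n11_pair(const RawVector& a, const RawVector& b) {
  if (a.size() != b.size()) stop("packed series have different lengths");
  if (a.size() % 8 != 0) stop("packed buffer not padded to 64-bit words");
  const R_xlen_t W = a.size() / 8;
  uint64_t wa, wb;
  int n = 0;
  for (R_xlen_t j = 0; j < W; ++j) {
    std::memcpy(&wa, &a[8 * j], 8);
    std::memcpy(&wb, &b[8 * j], 8);
    n += pop64(wa & wb);
  }
  return n;
}

// Upper-triangular (i < j, row-major) joint-ones counts for all pairs.
// [[Rcpp::export]]
IntegerVector cpp_n11_tri(const RawVector& packed, int V, int T) {
  const R_xlen_t B = bytes_per_series(T);
  const R_xlen_t W = B / 8;
  if (static_cast<R_xlen_t>(packed.size()) != B * V)
    stop("packed buffer has unexpected size");
  // copy into an aligned uint64 buffer once; avoids per-pair memcpy
  std::vector<uint64_t> words(static_cast<size_t>(W) * V);
  for (int v = 0; v < V; ++v)
    std::memcpy(&words[static_cast<size_t>(v) * W],
                &packed[static_cast<R_xlen_t>(v) * B], B);
  const R_xlen_t np = static_cast<R_xlen_t>(V) * (V - 1) / 2;
  IntegerVector out(np);
  R_xlen_t idx = 0;
  for (int i = 0; i < V; ++i) {
    const uint64_t* wi = &words[static_cast<size_t>(i) * W];
    for (int j = i + 1; j < V; ++j) {
      const uint64_t* wj = &words[static_cast<size_t>(j) * W];
      int n = 0;
      for (R_xlen_t k = 0; k < W; ++k) n += pop64(wi[k] & wj[k]);
      out[idx++] = n;
    }
  }
  return out;
}

// Blocked Pearson correlation triangle (i < j, row-major). Per-voxel means
// and centred norms are precomputed once; the pair loop runs over square
// blocks so each block's rows stay cache-resident. Zero-variance rows give
// NA entries.
// [[Rcpp::export]]
NumericVector cpp_pearson_tri(const NumericMatrix& ts, int block) {
  const int V = ts.nrow(), T = ts.ncol();
  if (V < 2) stop("need at least two series");
  if (block < 1) stop("block must be positive");
  std::vector<double> Z(static_cast<size_t>(V) * T);  // centred, row-major
  std::vector<double> inv(V);
  std::vector<bool> degen(V);
  for (int v = 0; v < V; ++v) {
    double m = 0;
    for (int k = 0; k < T; ++k) m += ts(v, k);
    m /= T;
    double ss = 0;
    double* zr = &Z[static_cast<size_t>(v) * T];
    for (int k = 0; k < T; ++k) {
      const double c = ts(v, k) - m;
      zr[k] = c;
      ss += c * c;
    }
    degen[v] = (ss == 0.0);
    inv[v] = degen[v] ? 0.0 : 1.0 / std::sqrt(ss);
  }
  const R_xlen_t np = static_cast<R_xlen_t>(V) * (V - 1) / 2;
  NumericVector out(np);
  for (int ib = 0; ib < V; ib += block) {
    const int iend = std::min(ib + block, V);
    for (int jb = ib; jb < V; jb += block) {
      const int jend = std::min(jb + block, V);
      for (int i = ib; i < iend; ++i) {
        const double* zi = &Z[static_cast<size_t>(i) * T];
        const R_xlen_t base =
            static_cast<R_xlen_t>(i) * V - static_cast<R_xlen_t>(i) * (i + 1) / 2 - i - 1;
        for (int j = std::max(jb, i + 1); j < jend; ++j) {
          if (degen[i] || degen[j]) {
            out[base + j] = NA_REAL;
            continue;
          }
          const double* zj = &Z[static_cast<size_t>(j) * T];
          double s = 0;
          for (int k = 0; k < T; ++k) s += zi[k] * zj[k];
          double r = s * inv[i] * inv[j];
          if (r > 1.0) r = 1.0;
          if (r < -1.0) r = -1.0;
          out[base + j] = r;
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_col_medians(const NumericMatrix& x) {
  const int T = x.nrow(), n = x.ncol();
  if (T < 1) stop("empty matrix");
  NumericVector out(n);
  std::vector<double> buf(T);
  for (int j = 0; j < n; ++j) {
    for (int k = 0; k < T; ++k) buf[k] = x(k, j);
    const int h = T / 2;
    std::nth_element(buf.begin(), buf.begin() + h, buf.end());
    double m = buf[h];
    if (T % 2 == 0) {
      const double lo = *std::max_element(buf.begin(), buf.begin() + h);
      m = (m + lo) / 2.0;
    }
    out[j] = m;
  }
  return out;
}
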