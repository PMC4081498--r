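# Independent brute-force oracles used throughout the suite. These never
# touch the packed/blocked code paths they are checking.

# Pearson triangle by double loop over stats::cor
naive_pearson_tri <- function(ts) {
  V <- nrow(ts)
  out <- numeric(V * (V - 1) / 2)
  p <- 1L
  for (i in seq_len(V - 1L)) {
    for (j in (i + 1L):V) {
      out[p] <- suppressWarnings(stats::cor(ts[i, ], ts[j, ]))
      p <- p + 1L
    }
  }
  out
}

# tetrachoric triangle from unpacked 0/1 bits: n11 by explicit dot product,
# then the closed form on p11
naive_rt_tri <- function(bits) {
  V <- nrow(bits)
  T <- ncol(bits)
  out <- numeric(V * (V - 1) / 2)
  p <- 1L
  for (i in seq_len(V - 1L)) {
    for (j in (i + 1L):V) {
      n11 <- sum(bits[i, ] * bits[j, ])
      out[p] <- -cos(2 * pi * (n11 / T))
      p <- p + 1L
    }
  }
  out
}

# all unordered pairs (i < j) in row-major order
tri_pairs <- function(V) {
  i <- rep.int(seq_len(V - 1L), (V - 1L):1L)
  j <- sequence((V - 1L):1L) + i
  cbind(i = i, j = j)
}

random_binary_matrix <- function(V, T) {
  matrix(sample(0:1, V * T, replace = TRUE), V, T)
}
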