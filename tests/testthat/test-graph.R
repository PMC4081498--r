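make_triangle <- function(values, V, estimator = "r") {
  fcgraph:::new_cor_triangle(values, V, estimator)
}

test_that("density thresholding selects the top pairs at the target kappa", {
  # pairs in row-major order: (1,2) (1,3) (1,4) (2,3) (2,4) (3,4)
  C <- make_triangle(c(0.9, 0.1, 0.2, 0.8, 0.3, 0.7), 4)
  G <- density_threshold(C, 1 / 3)
  expect_identical(nrow(G$edges), 2L)         # top-2 of 6 pairs
  expect_setequal(paste(G$edges[, 1], G$edges[, 2]), c("1 2", "2 3"))
  expect_gt(G$theta, 0.7)
  expect_lt(G$theta, 0.8)
  expect_equal(G$kappa, 1 / 3)
  # near the feasible limit every pair becomes an edge
  G_all <- density_threshold(C, 0.999)
  expect_identical(nrow(G_all$edges), 6L)
})

test_that("realized density is within one edge of the target", {
  set.seed(31)
  V <- 200L
  np <- V * (V - 1L) / 2L
  C <- make_triangle(runif(np, -1, 1), V)
  G <- density_threshold(C, 0.01)
  m <- nrow(G$edges)
  expect_lte(abs(m - 0.01 * np), 1)
  # selection oracle: full sort picks the same values
  expect_setequal(C$values[tri_index(G$edges[, 1], G$edges[, 2], V)],
                  sort(C$values, decreasing = TRUE)[seq_len(m)])
  # strict c > theta rule reproduces the edge set on tie-free values
  expect_identical(sum(C$values > G$theta), m)
})

test_that("edge sets nest as density grows", {
  set.seed(32)
  C <- make_triangle(runif(4950, -1, 1), 100L)
  keys <- function(G) paste(G$edges[, 1], G$edges[, 2])
  e1 <- keys(density_threshold(C, 0.01))
  e2 <- keys(density_threshold(C, 0.05))
  e3 <- keys(density_threshold(C, 0.2))
  expect_true(all(e1 %in% e2))
  expect_true(all(e2 %in% e3))
})

test_that("thresholding honours the missing-mask and feasibility", {
  vals <- c(0.9, NA, 0.2, NA, 0.3, 0.7)
  C <- make_triangle(vals, 4)
  G <- density_threshold(C, 1 / 3)
  expect_setequal(paste(G$edges[, 1], G$edges[, 2]), c("1 2", "3 4"))
  expect_error(density_threshold(C, 0.9), "non-missing")
  expect_error(density_threshold(C, 0), "kappa")
  expect_error(density_threshold(make_triangle(rep(NA_real_, 6), 4), 0.3),
               "no non-missing")
})

test_that("degrees count incident edges and sum to twice the edge count", {
  tri <- make_triangle(c(0.9, 0.8, 0.1, 0.7, 0.1, 0.1), 4)
  G <- density_threshold(tri, 0.5)  # triangle on nodes 1,2,3
  expect_identical(graph_degree(G), c(2L, 2L, 2L, 0L))
  # star on 5 nodes: center gets V-1, leaves 1
  star <- matrix(-1, 5, 5)
  star[1, 2:5] <- star[2:5, 1] <- 0.9
  Cs <- make_triangle(as.numeric(star[cbind(tri_pairs(5)[, 1],
                                            tri_pairs(5)[, 2])]), 5)
  Gs <- density_threshold(Cs, 0.4)
  expect_identical(graph_degree(Gs), c(4L, 1L, 1L, 1L, 1L))
  # random graph: degrees match adjacency row sums
  set.seed(33)
  C <- make_triangle(runif(4950, -1, 1), 100L)
  G <- density_threshold(C, 0.05)
  adj <- matrix(0L, 100, 100)
  adj[G$edges] <- 1L
  adj <- adj + t(adj)
  expect_identical(graph_degree(G), as.integer(rowSums(adj)))
  expect_identical(sum(graph_degree(G)), 2L * nrow(G$edges))
})

test_that("degree standardization z-scores with the population sd", {
  expect_error(standardize_degrees(c(2, 2, 2)), "variance")
  expect_equal(standardize_degrees(c(0, 2)), c(-1, 1))
  k <- c(0, 1, 3, 8, 2)
  z <- standardize_degrees(k)
  expect_equal(mean(z), 0)
  expect_equal(mean(z^2), 1)                      # unit population variance
  expect_equal(standardize_degrees(k + 5), z)     # location invariance
})

test_that("group averaging drops weakly supported voxels", {
  dims <- c(4L, 4L, 3L)
  base <- array(rnorm(prod(dims)), dims)
  # five identical full-coverage maps reproduce the input
  gk <- group_average(replicate(5, base, simplify = FALSE))
  expect_equal(gk$mean, base)
  expect_true(all(gk$support == 5L))
  # voxel supported by 1 of 10 subjects is discarded at the 20% cutoff
  maps <- replicate(10, {
    m <- base
    m[1, 1, 1] <- NA
    m
  }, simplify = FALSE)
  maps[[1]][1, 1, 1] <- 99
  gk <- group_average(maps, support_fraction = 0.2)
  expect_true(is.na(gk$mean[1, 1, 1]))
  expect_identical(gk$support[1, 1, 1], 1L)
  expect_error(group_average(list()), "empty")
  expect_error(group_average(list(base, array(0, c(2, 2, 2)))), "shared grid")
})

test_that("staggered masks average to the per-voxel loop oracle", {
  set.seed(34)
  dims <- c(5L, 4L, 2L)
  maps <- replicate(6, {
    m <- array(rnorm(prod(dims)), dims)
    m[sample(prod(dims), 10)] <- NA
    m
  }, simplify = FALSE)
  gk <- group_average(maps, support_fraction = 0.3)
  for (v in seq_len(prod(dims))) {
    vals <- vapply(maps, function(m) m[[v]], numeric(1))
    sup <- sum(!is.na(vals))
    expected <- if (sup < 0.3 * 6) NA_real_ else mean(vals, na.rm = TRUE)
    expect_equal(gk$mean[[v]], expected)
  }
})

test_that("degree tables and edge-list files round-trip", {
  set.seed(35)
  C <- make_triangle(runif(45, -1, 1), 10L)
  G <- density_threshold(C, 0.2)
  dm <- degree_map(G)
  expect_identical(dm$degree, graph_degree(G))
  expect_equal(dm$z, standardize_degrees(graph_degree(G)))
  path <- file.path(tempdir(), "edges.txt")
  write_edgelist(G, path)
  G2 <- read_edgelist(path)
  expect_identical(G2$edges[, 1], G$edges[, 1])
  expect_identical(G2$edges[, 2], G$edges[, 2])
  expect_equal(G2$theta, G$theta)
  # file itself is 0-based
  raw <- utils::read.table(path)
  expect_identical(as.integer(raw[[1]]), G$edges[, 1] - 1L)
})
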