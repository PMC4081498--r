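test_that("bivariate sampling hits the requested correlation at scale", {
  s0 <- sample_bivariate(0, 1e6, seed = 41)
  expect_lt(abs(cor(s0$x, s0$y)), 0.005)
  s99 <- sample_bivariate(0.99, 1e5, seed = 42)
  expect_lt(abs(cor(s99$x, s99$y) - 0.99), 0.01)
  expect_identical(sample_bivariate(0.5, 100, seed = 7),
                   sample_bivariate(0.5, 100, seed = 7))
  expect_error(sample_bivariate(1, 10), "rho")
})

test_that("the closed-form Pearson bias evaluates correctly", {
  expect_equal(expected_r_bias(0, 100), 0)
  expect_equal(expected_r_bias(1, 50), 0)
  expect_equal(expected_r_bias(-1, 50), 0)
  expect_equal(expected_r_bias(0.5, 100), -0.001875)
  expect_equal(expected_r_bias(-0.5, 100), 0.001875)
})

test_that("Deming regression recovers exact linear relations", {
  x <- seq(-1, 1, length.out = 20)
  f1 <- deming_fit(x, x)
  expect_equal(f1$slope, 1)
  expect_equal(f1$intercept, 0)
  f2 <- deming_fit(x, 2 * x + 1)
  expect_equal(f2$slope, 2)
  expect_equal(f2$intercept, 1)
  expect_error(deming_fit(rep(1, 5), 1:5), "variance")
  td <- tidy(f2)
  expect_identical(td$term, c("intercept", "slope"))
  expect_equal(td$estimate, c(1, 2))
})

test_that("Deming resists the attenuation that biases OLS", {
  set.seed(43)
  n <- 1e4
  latent <- rnorm(n)
  x <- latent + rnorm(n, sd = 0.5)
  y <- latent + rnorm(n, sd = 0.5)   # equal noise on both axes, true slope 1
  fit <- deming_fit(x, y)
  expect_lt(abs(fit$slope - 1), 0.02)
  ols <- unname(coef(lm(y ~ x))[2])
  expect_lt(ols, 0.85)               # OLS attenuates well below 1
  # slope(x,y) = 1/slope(y,x) for the orthogonal fit
  expect_equal(fit$slope, 1 / deming_fit(y, x)$slope, tolerance = 1e-10)
})

test_that("joint histograms bin on grid centers and conserve counts", {
  h <- joint_histogram(0, 0)
  expect_identical(sum(h), 1L)
  expect_identical(h[100, 100], 1L)   # (0, 0) is the central bin
  # values exactly at bin centers land in their own bin
  g <- rho_grid()
  h2 <- joint_histogram(g, g)
  expect_identical(unname(diag(h2)), rep(1L, 199))
  set.seed(44)
  a <- runif(5000, -1, 1); b <- runif(5000, -1, 1)
  expect_identical(sum(joint_histogram(a, b)), 5000L)
})

test_that("the rho grid matches the study design", {
  g <- rho_grid()
  expect_length(g, 199L)
  expect_equal(diff(g), rep(0.01, 198))
  expect_equal(g, -rev(g))           # symmetric about 0
  expect_equal(range(g), c(-0.99, 0.99))
})

test_that("a single-replicate study reproduces the documented draw", {
  T <- 50L
  st <- run_study(T, n_reps = 1L, grid = c(0.3), seed = 45)
  set.seed(45)
  x <- rnorm(T)
  y <- 0.3 * x + sqrt(1 - 0.3^2) * rnorm(T)
  r <- pearson_pair(x, y)
  n11 <- sum((x >= median(x)) & (y >= median(y)))
  rt <- tetrachoric_from_n11(n11, T)
  expect_equal(st$stats$mean[st$stats$estimator == "r"], r)
  expect_equal(st$stats$mean[st$stats$estimator == "r_t"], rt)
})

test_that("per-bin aggregates satisfy the study invariants", {
  st <- run_study(100L, n_reps = 400L, grid = c(-0.9, -0.5, 0, 0.5, 0.9),
                  seed = 46)
  tb <- tidy(st)
  expect_identical(tb$n, rep(400, 10))
  # MSD is mean minus rho, by definition
  expect_equal(tb$msd, tb$mean - tb$rho)
  # histograms conserve all samples
  expect_identical(sum(st$hist_r_rho), 5L * 400L)
  expect_identical(sum(st$hist_rt_rho), 5L * 400L)
  expect_identical(sum(st$hist_rt_r), 5L * 400L)
  # the dichotomized estimator is noisier in every bin
  sd_r <- tb$sd[tb$estimator == "r"]
  sd_rt <- tb$sd[tb$estimator == "r_t"]
  expect_true(all(sd_rt > sd_r))
  # determinism under a fixed seed
  st2 <- run_study(100L, n_reps = 400L, grid = c(-0.9, -0.5, 0, 0.5, 0.9),
                   seed = 46)
  expect_equal(st$stats, st2$stats)
  expect_equal(st$correlations, st2$correlations)
})

test_that("larger samples shrink the per-bin spread", {
  grid <- c(-0.5, 0, 0.5)
  st100 <- run_study(100L, n_reps = 1000L, grid = grid, seed = 47)
  st300 <- run_study(300L, n_reps = 1000L, grid = grid, seed = 48)
  expect_true(all(st300$stats$sd < st100$stats$sd))
})

test_that("accumulated grid-wide correlations match direct computation", {
  # tiny study recomputed by brute force from the same seeded draws
  grid <- c(-0.6, 0, 0.6)
  T <- 40L; reps <- 200L
  st <- run_study(T, n_reps = reps, grid = grid, seed = 49)
  set.seed(49)
  r_all <- c(); rt_all <- c(); rho_all <- c()
  for (rho in grid) {
    x <- matrix(rnorm(T * reps), T, reps)
    y <- rho * x + sqrt(1 - rho^2) * matrix(rnorm(T * reps), T, reps)
    for (s in seq_len(reps)) {
      r_all <- c(r_all, pearson_pair(x[, s], y[, s]))
      n11 <- sum((x[, s] >= median(x[, s])) & (y[, s] >= median(y[, s])))
      rt_all <- c(rt_all, tetrachoric_from_n11(n11, T))
      rho_all <- c(rho_all, rho)
    }
  }
  gc <- grid_correlations(st)
  expect_equal(gc$correlation[gc$pair == "r_rho"], cor(r_all, rho_all))
  expect_equal(gc$correlation[gc$pair == "rt_rho"], cor(rt_all, rho_all))
  expect_equal(gc$correlation[gc$pair == "rt_r"], cor(rt_all, r_all))
  # Deming fit from accumulators equals the direct fit on all pairs
  direct <- deming_fit(rt_all, r_all)
  expect_equal(st$deming$slope, direct$slope)
  expect_equal(st$deming$intercept, direct$intercept)
})

test_that("study tables serialize as delimited text", {
  st <- run_study(50L, n_reps = 20L, grid = c(0), seed = 50,
                  keep_histograms = FALSE)
  path <- file.path(tempdir(), "study.tsv")
  write_study(st, path)
  back <- utils::read.table(path, header = TRUE, sep = "\t")
  expect_identical(nrow(back), 2L)
  expect_equal(back$mean, st$stats$mean)
})
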