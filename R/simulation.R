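#' The simulation grid of population correlations
#'
#' 199 evenly spaced values from -0.99 to 0.99 in steps of 0.01, symmetric
#' about 0; these are both the populations sampled in [run_study()] and the
#' histogram bin centers used by [joint_histogram()].
#'
#' @return Numeric vector of length 199.
#' @export
rho_grid <- function() {
  round(seq(-99L, 99L) / 100, 2)
}

#' Draw one bivariate-normal sample
#'
#' Unit marginals, population correlation `rho`; constructed as
#' y = rho * x + sqrt(1 - rho^2) * z with independent standard normals.
#'
#' @param rho Population correlation, |rho| < 1.
#' @param T Sample size (pairs).
#' @param seed Optional integer seed for reproducibility.
#' @return Tibble with columns `x`, `y` of length `T`.
#' @export
sample_bivariate <- function(rho, T, seed = NULL) {
  if (abs(rho) >= 1) stop("|rho| must be < 1")
  stopifnot(T >= 2)
  if (!is.null(seed)) set.seed(seed)
  x <- stats::rnorm(T)
  y <- rho * x + sqrt(1 - rho^2) * stats::rnorm(T)
  tibble::tibble(x = x, y = y)
}

#' Approximate bias of Pearson's r under bivariate normality
#'
#' Uses the classical expansion E(r) = rho - rho(1 - rho^2)/(2n), so the
#' returned bias E(r) - rho is -rho(1 - rho^2)/(2n): zero at rho = 0 and
#' rho = +/-1, largest in magnitude in between.
#'
#' @param rho Population correlation(s), |rho| <= 1.
#' @param n Sample size, >= 2.
#' @return Bias value(s).
#' @export
expected_r_bias <- function(rho, n) {
  stopifnot(all(abs(rho) <= 1), n >= 2)
  -rho * (1 - rho^2) / (2 * n)
}

#' Deming (errors-in-variables) regression
#'
#' Fits y = intercept + slope * x assuming noise in both coordinates with
#' error-variance ratio `delta` (delta = 1 gives orthogonal regression, the
#' natural choice when both variables estimate the same quantity on the same
#' scale).
#'
#' @param x,y Numeric vectors, >= 3 points, both with nonzero variance.
#' @param delta Ratio of the y- to x-error variances; default 1.
#' @return A `deming_fit` list: `slope`, `intercept`, `delta`, `n`.
#' @export
deming_fit <- function(x, y, delta = 1) {
  stopifnot(length(x) == length(y), length(x) >= 3, delta > 0)
  deming_from_moments(mean(x), mean(y), stats::var(x), stats::var(y),
                      stats::cov(x, y), length(x), delta)
}

#' @importFrom stats cov
deming_from_moments <- function(mx, my, sxx, syy, sxy, n, delta = 1) {
  if (sxx == 0 || syy == 0) stop("zero variance: Deming fit undefined")
  slope <- if (sxy == 0) {
    0  # no association: flat line
  } else {
    (syy - delta * sxx + sqrt((syy - delta * sxx)^2 + 4 * delta * sxy^2)) /
      (2 * sxy)
  }
  structure(list(slope = slope, intercept = my - slope * mx,
                 delta = delta, n = n),
            class = "deming_fit")
}

#' @export
print.deming_fit <- function(x, ...) {
  cat("<deming_fit> slope =", signif(x$slope, 5),
      " intercept =", signif(x$intercept, 5),
      " delta =", x$delta, " n =", x$n, "\n")
  invisible(x)
}

#' @export
tidy.deming_fit <- function(x, ...) {
  tibble::tibble(term = c("intercept", "slope"),
                 estimate = c(x$intercept, x$slope))
}

#' @export
glance.deming_fit <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept,
                 delta = x$delta, n = x$n)
}

# 1-based bin index on the rho grid: half-open [low, high) bins with edges at
# midpoints between centers; the outer bins absorb everything out to +/-1.
grid_bin <- function(x, grid = rho_grid()) {
  mids <- (grid[-length(grid)] + grid[-1L]) / 2
  findInterval(x, mids) + 1L
}

#' Joint histogram on the simulation grid
#'
#' Counts pairs (a, b) on a 199 x 199 grid whose bin centers are the
#' [rho_grid()] values in both dimensions. Bins are half-open [low, high)
#' with edges at midpoints between centers; the outermost bins absorb
#' overflow out to +/-1, so the total count always equals the number of
#' input pairs.
#'
#' @param a,b Numeric vectors of equal length (rows index `a`, columns `b`).
#' @param grid Bin centers; default [rho_grid()].
#' @return Integer matrix `length(grid)` x `length(grid)` with `dimnames`
#'   giving the centers.
#' @export
joint_histogram <- function(a, b, grid = rho_grid()) {
  stopifnot(length(a) == length(b))
  g <- length(grid)
  ia <- grid_bin(a, grid)
  ib <- grid_bin(b, grid)
  counts <- matrix(tabulate((ib - 1L) * g + ia, nbins = g * g), g, g)
  dimnames(counts) <- list(a = format(grid), b = format(grid))
  counts
}

#' Bivariate-normal estimator-comparison study
#'
#' For every population correlation rho on the grid, draws `n_reps`
#' independent bivariate-normal samples of size `T` and computes, per
#' sample, Pearson's r from the continuous pair and the tetrachoric rt from
#' the median-dichotomized pair (rt = -cos(2*pi*n11/T)). Per rho-bin means,
#' standard deviations and mean signed differences MSD(est, rho) =
#' mean(est) - rho are tabulated for both estimators; joint histograms
#' (r, rho), (rt, rho) and (rt, r) are accumulated on the grid, and a Deming
#' regression is fitted to the pooled (rt, r) pairs.
#'
#' @param T Sample size per draw (e.g. 100 or 300).
#' @param n_reps Samples per rho value; 10000 for the full study.
#' @param grid Population correlations; default [rho_grid()].
#' @param seed Optional integer seed.
#' @param keep_histograms Accumulate the three joint histograms (default
#'   TRUE; disable to save a little time and memory).
#' @return An `fc_sim_study`: list with `stats` (tibble: rho, estimator,
#'   mean, sd, msd, n), `deming` (fit to (rt, r)), `correlations` (tibble of
#'   grid-wide estimator correlations, see [grid_correlations()]),
#'   histograms `hist_r_rho`, `hist_rt_rho`, `hist_rt_r` (or NULL), plus
#'   `T`, `n_reps`, `grid`, `seed`.
#' @export
run_study <- function(T, n_reps = 10000L, grid = rho_grid(), seed = NULL,
                      keep_histograms = TRUE) {
  stopifnot(T >= 2, n_reps >= 1)
  if (!is.null(seed)) set.seed(seed)
  g <- length(grid)
  acc <- matrix(0, g, 7L,
                dimnames = list(NULL, c("sum_r", "sum_r2", "sum_rt",
                                        "sum_rt2", "sum_r_rt", "n", "rho")))
  if (keep_histograms) {
    h_r_rho <- matrix(0L, g, g)
    h_rt_rho <- matrix(0L, g, g)
    h_rt_r <- matrix(0L, g, g)
  }
  for (b in seq_len(g)) {
    rho <- grid[b]
    x <- matrix(stats::rnorm(T * n_reps), T, n_reps)
    y <- rho * x + sqrt(1 - rho^2) * matrix(stats::rnorm(T * n_reps), T, n_reps)
    # Pearson r per column
    cx <- x - rep(colMeans(x), each = T)
    cy <- y - rep(colMeans(y), each = T)
    r <- colSums(cx * cy) / sqrt(colSums(cx^2) * colSums(cy^2))
    # median dichotomization of each margin, then the closed form
    dx <- x >= rep(cpp_col_medians(x), each = T)
    dy <- y >= rep(cpp_col_medians(y), each = T)
    rt <- tetrachoric_from_n11(colSums(dx & dy), T)
    acc[b, ] <- c(sum(r), sum(r^2), sum(rt), sum(rt^2), sum(r * rt),
                  n_reps, rho)
    if (keep_histograms) {
      ir <- grid_bin(r, grid)
      irt <- grid_bin(rt, grid)
      h_r_rho[, b] <- h_r_rho[, b] + tabulate(ir, g)
      h_rt_rho[, b] <- h_rt_rho[, b] + tabulate(irt, g)
      h_rt_r <- h_rt_r + matrix(tabulate((ir - 1L) * g + irt, g * g), g, g)
    }
  }
  n <- acc[, "n"]
  mean_r <- acc[, "sum_r"] / n
  mean_rt <- acc[, "sum_rt"] / n
  sd_of <- function(s, s2, m) sqrt(pmax(0, (s2 - n * m^2) / (n - 1)))
  stats_tbl <- tibble::tibble(
    rho = rep(grid, 2L),
    estimator = rep(c("r", "r_t"), each = g),
    mean = unname(c(mean_r, mean_rt)),
    sd = unname(c(sd_of(acc[, "sum_r"], acc[, "sum_r2"], mean_r),
                  sd_of(acc[, "sum_rt"], acc[, "sum_rt2"], mean_rt))),
    msd = unname(c(mean_r - grid, mean_rt - grid)),
    n = unname(rep(n, 2L))
  )
  # pooled moments over all g * n_reps samples
  N <- sum(n)
  pool <- function(s) sum(s) / N
  m_r <- pool(acc[, "sum_r"]); m_rt <- pool(acc[, "sum_rt"])
  m_rho <- sum(n * grid) / N
  cov_p <- function(sxy, mx, my) sxy / N - mx * my
  v_r <- cov_p(sum(acc[, "sum_r2"]), m_r, m_r)
  v_rt <- cov_p(sum(acc[, "sum_rt2"]), m_rt, m_rt)
  v_rho <- sum(n * grid^2) / N - m_rho^2
  c_r_rho <- cov_p(sum(acc[, "sum_r"] * grid), m_r, m_rho)
  c_rt_rho <- cov_p(sum(acc[, "sum_rt"] * grid), m_rt, m_rho)
  c_rt_r <- cov_p(sum(acc[, "sum_r_rt"]), m_rt, m_r)
  correlations <- tibble::tibble(
    pair = c("r_rho", "rt_rho", "rt_r"),
    correlation = unname(c(c_r_rho / sqrt(v_r * v_rho),
                           c_rt_rho / sqrt(v_rt * v_rho),
                           c_rt_r / sqrt(v_rt * v_r)))
  )
  deming <- if (N >= 3 && is.finite(v_r) && is.finite(v_rt) &&
                v_r > 0 && v_rt > 0) {
    deming_from_moments(m_rt, m_r,
                        v_rt * N / (N - 1), v_r * N / (N - 1),
                        c_rt_r * N / (N - 1), N)
  } else {
    NULL  # too few samples for an errors-in-variables fit
  }
  structure(
    list(stats = stats_tbl, correlations = correlations, deming = deming,
         hist_r_rho = if (keep_histograms) h_r_rho else NULL,
         hist_rt_rho = if (keep_histograms) h_rt_rho else NULL,
         hist_rt_r = if (keep_histograms) h_rt_r else NULL,
         T = as.integer(T), n_reps = as.integer(n_reps),
         grid = grid, seed = seed),
    class = "fc_sim_study"
  )
}

#' @export
print.fc_sim_study <- function(x, ...) {
  cat("<fc_sim_study> T =", x$T, " n_reps =", x$n_reps,
      " bins =", length(x$grid), "\n")
  at0 <- x$stats[x$stats$rho == 0, ]
  if (nrow(at0)) {
    cat("  SD at rho=0:",
        paste(sprintf("%s=%.4f", at0$estimator, at0$sd), collapse = "  "),
        "\n")
  }
  cat("  grid-wide correlations:",
      paste(sprintf("%s=%.4f", x$correlations$pair,
                    x$correlations$correlation), collapse = "  "), "\n")
  invisible(x)
}

#' Per-bin study statistics
#'
#' @param x An `fc_sim_study`.
#' @param ... Unused.
#' @return The per-bin tibble (rho, estimator, mean, sd, msd, n).
#' @export
tidy.fc_sim_study <- function(x, ...) x$stats

#' @export
glance.fc_sim_study <- function(x, ...) {
  w <- function(p) x$correlations$correlation[x$correlations$pair == p]
  tibble::tibble(T = x$T, n_reps = x$n_reps,
                 sd_r_rho0 = x$stats$sd[x$stats$rho == 0 &
                                          x$stats$estimator == "r"],
                 sd_rt_rho0 = x$stats$sd[x$stats$rho == 0 &
                                           x$stats$estimator == "r_t"],
                 cor_r_rho = w("r_rho"), cor_rt_rho = w("rt_rho"),
                 cor_rt_r = w("rt_r"),
                 deming_slope = if (is.null(x$deming)) NA_real_
                                else x$deming$slope,
                 deming_intercept = if (is.null(x$deming)) NA_real_
                                    else x$deming$intercept)
}

#' Grid-wide estimator correlations
#'
#' Pearson correlations over all (sample, rho) pairs of the study: estimate
#' vs rho for each estimator, and rt vs r, computed from the per-bin moment
#' accumulators (no per-sample storage needed).
#'
#' @param study An `fc_sim_study`.
#' @return Tibble with columns `pair` (`r_rho`, `rt_rho`, `rt_r`) and
#'   `correlation`.
#' @export
grid_correlations <- function(study) {
  stopifnot(inherits(study, "fc_sim_study"))
  study$correlations
}

#' Write the per-bin study table as delimited text
#'
#' @param study An `fc_sim_study`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_study <- function(study, path) {
  stopifnot(inherits(study, "fc_sim_study"))
  utils::write.table(study$stats, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
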