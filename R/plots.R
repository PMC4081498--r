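#' Plot a simulation study
#'
#' `type = "summary"` shows per-bin mean +/- SD of each estimator against
#' the population correlation; `"bias"` overlays the per-bin mean signed
#' differences with the closed-form Pearson bias approximation
#' -rho(1 - rho^2)/(2n); `"histogram"` renders the pooled (rt, r) joint
#' histogram with the Deming regression line.
#'
#' @param object An `fc_sim_study`.
#' @param type One of `"summary"`, `"bias"`, `"histogram"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fc_sim_study <- function(object,
                                  type = c("summary", "bias", "histogram"),
                                  ...) {
  type <- match.arg(type)
  st <- object$stats
  if (type == "summary") {
    ggplot2::ggplot(st, ggplot2::aes(x = .data$rho)) +
      ggplot2::geom_ribbon(
        ggplot2::aes(ymin = .data$mean - .data$sd,
                     ymax = .data$mean + .data$sd,
                     fill = .data$estimator), alpha = 0.3) +
      ggplot2::geom_line(ggplot2::aes(y = .data$mean,
                                      colour = .data$estimator)) +
      ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
      ggplot2::labs(x = expression(rho), y = "estimate (mean ± SD)",
                    title = sprintf("Estimator comparison, T = %d", object$T))
  } else if (type == "bias") {
    closed <- tibble::tibble(
      rho = object$grid,
      bias = expected_r_bias(object$grid, object$T))
    ggplot2::ggplot(st, ggplot2::aes(x = .data$rho, y = .data$msd,
                                     colour = .data$estimator)) +
      ggplot2::geom_line() +
      ggplot2::geom_line(data = closed,
                         mapping = ggplot2::aes(x = .data$rho,
                                                y = .data$bias),
                         colour = "black", linetype = 2,
                         inherit.aes = FALSE) +
      ggplot2::labs(x = expression(rho), y = "mean signed difference",
                    title = sprintf("Empirical bias vs closed form, T = %d",
                                    object$T))
  } else {
    if (is.null(object$hist_rt_r)) {
      stop("study was run with keep_histograms = FALSE")
    }
    h <- object$hist_rt_r
    df <- tibble::tibble(
      rt = rep(object$grid, times = length(object$grid)),
      r = rep(object$grid, each = length(object$grid)),
      count = as.vector(h))
    df <- df[df$count > 0, ]
    ggplot2::ggplot(df, ggplot2::aes(x = .data$rt, y = .data$r,
                                     fill = .data$count)) +
      ggplot2::geom_raster() +
      ggplot2::scale_fill_gradient(low = "grey90", high = "black",
                                   trans = "log10") +
      ggplot2::geom_abline(slope = object$deming$slope,
                           intercept = object$deming$intercept,
                           colour = "orange", linetype = 2) +
      ggplot2::labs(x = expression(r[t]), y = "r",
                    title = sprintf("Joint histogram (r_t, r), T = %d",
                                    object$T))
  }
}

#' Plot a degree map slice
#'
#' Renders one axial slice of standardized node degrees placed back into
#' volume space.
#'
#' @param G An `fc_graph`.
#' @param mask A `voxel_mask` matching the graph's nodes.
#' @param slice Axial (third-dimension) slice index; default the middle.
#' @return A ggplot object.
#' @export
plot_degree_slice <- function(G, mask, slice = NULL) {
  dm <- degree_map(G, mask)
  if (is.null(slice)) slice <- round(mask$dim[3L] / 2)
  df <- dm[dm$z_vox == slice, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$z)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "z(k)") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("Standardized degree, slice z = %d", slice))
}

#' @importFrom ggplot2 .data
NULL
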