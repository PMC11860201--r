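#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a fitted power-law size spectrum
#'
#' Observed bin abundances and the fitted `y = b * x^-alpha` line on log-log
#' axes, the standard presentation for particle-size spectra.
#'
#' @param object A [fit_power_law()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.power_law_fit <- function(object, ...) {
  d <- object$data
  grid <- tibble::tibble(
    size = exp(seq(log(min(d$size)), log(max(d$size)), length.out = 100)))
  grid$abundance <- object$b * grid$size^(-object$alpha)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$size, y = .data$abundance)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "Particle size (µm)", y = "Relative abundance (%)",
      title = sprintf("Power-law fit%s: α = %.2f, R² = %.3f",
                      if (!is.null(object$site_label)) {
                        paste0(" — ", object$site_label)
                      } else "",
                      object$alpha, object$r_squared)) +
    ggplot2::theme_minimal()
}

#' Plot cumulative risk distributions
#'
#' Empirical cumulative distribution of a simulated risk metric per
#' receptor on a log scale, the standard way exceedance of regulatory
#' thresholds is read off Monte Carlo risk output.
#'
#' @param object A [run_simulation()] result.
#' @param metric `"ECR"`, `"HQ"` or `"ADD"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.risk_result <- function(object, metric = "ECR", ...) {
  rd <- object$receptor_draws
  if (!metric %in% c("ECR", "HQ", "ADD")) {
    stop("unknown metric '", metric, "'", call. = FALSE)
  }
  d <- rd[rd[[metric]] > 0, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data[[metric]],
                                  colour = .data$receptor)) +
    ggplot2::stat_ecdf() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = metric, y = "Cumulative probability",
                  colour = "Receptor") +
    ggplot2::theme_minimal()
}

#' Plot a sensitivity tornado chart
#'
#' Signed contribution-to-variance per input, ordered by magnitude.
#'
#' @param object A [sensitivity_analysis()] report.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sensitivity_report <- function(object, ...) {
  d <- dplyr::mutate(
    object,
    input = stats::reorder(.data$input, abs(.data$contribution_pct)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$contribution_pct,
                                  y = .data$input,
                                  fill = .data$contribution_pct > 0)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(x = "Contribution to variance (%)", y = NULL) +
    ggplot2::theme_minimal()
}
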