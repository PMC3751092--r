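#' Plot a performance metric across the scenario grid
#'
#' Line plot of one metric against the missingness proportion, coloured by
#' method, faceted by mechanism (columns) and analysis model (rows) -- the
#' layout in which simulation studies of missing-data methods usually
#' present bias, empirical SE and coverage. Requires ggplot2.
#'
#' @param metrics Metrics data.frame from [run_grid()] or stacked
#'   [run_cell()] results.
#' @param metric One of `"bias"`, `"emp_se"`, `"coverage"`.
#' @param true_hr Optional filter when `metrics` spans several hazard
#'   ratios.
#' @return A ggplot object.
#' @export
plot_metrics <- function(metrics, metric = c("bias", "emp_se", "coverage"),
                         true_hr = NULL) {
  metric <- match.arg(metric)
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_metrics() requires the ggplot2 package")
  if (!is.null(true_hr)) metrics <- metrics[metrics$true_hr == true_hr, ]
  lab <- c(bias = "Bias (log HR)",
           emp_se = "Empirical standard error",
           coverage = "Coverage of 95% CIs (%)")[[metric]]
  metrics$metric_value <- metrics[[metric]]
  p <- ggplot2::ggplot(
    metrics,
    ggplot2::aes(x = prop_missing, y = metric_value,
                 colour = method, group = method)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_grid(analysis ~ mechanism) +
    ggplot2::labs(x = "Proportion of missing wave-2 measurements",
                  y = lab, colour = "Method") +
    ggplot2::theme_bw()
  if (metric == "bias")
    p <- p + ggplot2::geom_hline(yintercept = 0, linetype = 2)
  if (metric == "coverage")
    p <- p + ggplot2::geom_hline(yintercept = 95, linetype = 2)
  p
}
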