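#' Plot an outcome measure over the design grid
#'
#' A basic faceted line plot of one outcome measure from a study summary
#' table (as produced by [run_study()]): the measure against the
#' population autocorrelation, one line per estimator, faceted by the
#' remaining design factors. Styling is intentionally minimal.
#'
#' @param summaries Summary data frame from [run_study()].
#' @param measure Column to plot; default `"bias_gamma01"`.
#' @return A ggplot object.
#' @export
plot_outcome <- function(summaries, measure = "bias_gamma01") {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  if (!measure %in% names(summaries))
    stop("unknown measure: ", measure)
  ggplot2::ggplot(
    summaries,
    ggplot2::aes(x = .data$gamma01, y = .data[[measure]],
                 colour = .data$estimator)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_grid(
      rows = ggplot2::vars(.data$T, .data$N),
      cols = ggplot2::vars(.data$sigma_u1),
      labeller = ggplot2::label_both) +
    ggplot2::labs(x = "population autocorrelation", y = measure) +
    ggplot2::theme_minimal()
}
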