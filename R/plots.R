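# ggplot2 views of the main result types.

#' Plot voltage traces
#'
#' @param traces tibble with \code{t}, \code{site}, \code{v} (e.g. from
#'   [run_nerve_shock()])
#' @return ggplot object
#' @export
plot_traces <- function(traces) {
  ggplot2::ggplot(traces, ggplot2::aes(.data$t, .data$v,
                                       colour = .data$site)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (ms)", y = "membrane potential (mV)") +
    ggplot2::theme_minimal()
}

#' Spike raster of a simulation
#'
#' @param spikes tibble with \code{cell}, \code{time}, optionally
#'   \code{type}
#' @export
plot_raster <- function(spikes) {
  p <- ggplot2::ggplot(spikes, ggplot2::aes(.data$time, .data$cell))
  if ("type" %in% names(spikes))
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data$type),
                                 shape = "|", size = 2)
  else p <- p + ggplot2::geom_point(shape = "|", size = 2)
  p + ggplot2::labs(x = "time (ms)", y = "cell") + ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.kernel_fit <- function(object, ...) {
  ggplot2::ggplot(object$kernel,
                  ggplot2::aes(.data$lag, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::labs(x = "lag (bins)", y = "kernel value (Hz per unit conc.)") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.morph_fit <- function(object, ...) {
  nb <- length(object$par$Fair)
  df <- tibble(
    bin = rep(seq_len(nb), 3),
    component = rep(c("F_air", "F_A", "F_B"), each = nb),
    value = c(object$par$Fair, object$par$FA, object$par$FB))
  ggplot2::ggplot(df, ggplot2::aes(.data$bin, .data$value,
                                   colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "cycle bin", y = "internal representation") +
    ggplot2::theme_minimal()
}

#' Histogram of phase correlations across schemes
#'
#' @param df tibble with \code{scheme} and \code{r}
#' @export
plot_phase_correlations <- function(df) {
  ggplot2::ggplot(df, ggplot2::aes(.data$r, fill = .data$scheme)) +
    ggplot2::geom_histogram(binwidth = 0.2, boundary = -1,
                            position = "dodge") +
    ggplot2::labs(x = "sister phase correlation (Pearson r)",
                  y = "count") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
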