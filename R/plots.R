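#' Plot a magnitude spectrum
#'
#' Line plot of magnitude against frequency, one facet-free line per channel
#' (capped for legibility).
#'
#' @param object An `eeg_spectrum`.
#' @param channels Indices of channels to draw (default first 8).
#' @param log_y Plot magnitudes on a log10 scale.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.eeg_spectrum <- function(object, channels = NULL, log_y = FALSE, ...) {
  if (is.null(channels)) channels <- seq_len(min(8L, nrow(object$magnitudes)))
  d <- purrr::map_dfr(channels, function(ch) {
    tibble::tibble(channel = sprintf("ch%02d", ch), freq = object$freqs,
                   magnitude = object$magnitudes[ch, ])
  })
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$freq, y = .data$magnitude,
                                       colour = .data$channel)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "frequency (Hz)", y = "magnitude",
                  title = sprintf("%s spectrum", object$origin)) +
    ggplot2::theme_minimal()
  if (log_y) p <- p + ggplot2::scale_y_log10()
  p
}

#' Compare per-method evaluation summaries
#'
#' Bar chart of mean accuracy for a named set of `eval_report`s, e.g. the
#' three baseline-removal strategies side by side.
#'
#' @param reports Named list of `eval_report` objects.
#' @return A ggplot object.
#' @export
plot_method_comparison <- function(reports) {
  d <- purrr::imap_dfr(reports, function(r, nm) {
    dplyr::mutate(glance(r), method = nm, .before = 1L)
  })
  ggplot2::ggplot(d, ggplot2::aes(x = .data$method, y = .data$mean_accuracy)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$mean_accuracy)),
                       vjust = -0.4) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "mean accuracy") +
    ggplot2::theme_minimal()
}
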