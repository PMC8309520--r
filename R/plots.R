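#' Plot a pupillary rhythm
#'
#' @param rhythm A [resample_rhythm()] tibble.
#' @return A ggplot object.
#' @export
plot_rhythm <- function(rhythm) {
  ggplot2::ggplot(rhythm, ggplot2::aes(x = .data$t_s, y = .data$diameter_px)) +
    ggplot2::geom_line(color = "#2c7fb8") +
    ggplot2::labs(x = "time (s)", y = "pupil diameter (px)",
                  title = "Pupillary rhythm (1 Hz)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.pupillary_rhythm <- function(object, ...) plot_rhythm(object)

#' Plot a rhythm power spectrum
#'
#' Marks the dominant peak whose share of band power defines the PRC
#' ratio.
#'
#' @param spectrum A [rhythm_spectrum()] tibble.
#' @return A ggplot object.
#' @export
plot_spectrum <- function(spectrum) {
  dom <- attr(spectrum, "dominant_bin")
  ggplot2::ggplot(spectrum, ggplot2::aes(x = .data$freq_hz, y = .data$power)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$freq_hz, yend = 0),
                          color = "grey40") +
    ggplot2::geom_point(data = spectrum[dom, ], color = "#d7301f", size = 2) +
    ggplot2::labs(x = "frequency (Hz)", y = "power",
                  title = "Pupillary rhythm spectrum (0-0.5 Hz)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.rhythm_spectrum <- function(object, ...) plot_spectrum(object)

#' Plot the ROC curve of a classifier evaluation
#'
#' @param eval An `ms_eval` result (or a tibble of `fpr`/`tpr` points).
#' @return A ggplot object.
#' @export
plot_roc <- function(eval) {
  roc <- if (inherits(eval, "ms_eval")) attr(eval, "roc") else eval
  ttl <- if (inherits(eval, "ms_eval")) {
    sprintf("ROC: %s (%s), AUC = %.2f", eval$classifier, eval$split, eval$auc)
  } else "ROC"
  ggplot2::ggplot(roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         color = "grey70") +
    ggplot2::geom_step(color = "#2c7fb8") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = ttl) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.ms_eval <- function(object, ...) plot_roc(object)

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
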