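#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a trial-averaged power spectrum
#'
#' Normalised power on a log scale against frequency, with the F1/F2 peak
#' frequencies marked.
#'
#' @param object A [power_spectrum()] result.
#' @param max_hz Upper frequency limit of the plot (default 25).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.flyssvep_spectrum <- function(object, max_hz = 25, ...) {
  peaks <- spectrum_peaks(object)
  df <- object[object$freq_hz <= max_hz, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$freq_hz, y = .data$power)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::geom_vline(xintercept = c(peaks$f1_hz, peaks$f2_hz),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "frequency (Hz)", y = "normalised power",
                  title = sprintf("F1 = %.2f Hz, F2 = %.2f Hz",
                                  peaks$f1_hz, peaks$f2_hz)) +
    ggplot2::theme_minimal()
}

#' Plot a fitted group comparison
#'
#' Box plots of the per-fly group means with individual fly points, the
#' style used for every amplitude contrast.
#'
#' @param object A [omnibus_test()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.flyssvep_comparison <- function(object, ...) {
  ggplot2::ggplot(object$fly_means,
                  ggplot2::aes(x = .data$group, y = .data$mean_amp)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.12, size = 1.6, alpha = 0.8) +
    ggplot2::labs(
      x = NULL, y = "amplitude (per-fly mean)",
      title = sprintf("%s%s: F = %.3g, p = %.3g (N = %d)",
                      object$contrast %||% "contrast",
                      if (is.na(object$region)) "" else
                        paste0(" [", object$region, "]"),
                      object$f_statistic, object$p_value, object$n_flies)) +
    ggplot2::theme_minimal()
}

#' Histogram of wake and sleep bout durations
#'
#' @param bouts A [score_bouts()] table (pooled across flies if a `fly_id`
#'   column is present).
#' @param binwidth_min Histogram bin width in minutes (default 2).
#' @return A ggplot object.
#' @export
plot_bout_durations <- function(bouts, binwidth_min = 2) {
  df <- dplyr::mutate(bouts, duration_min = .data$duration_s / 60)
  med <- dplyr::summarise(dplyr::group_by(df, .data$state),
                          m = stats::median(.data$duration_min),
                          .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$duration_min)) +
    ggplot2::geom_histogram(binwidth = binwidth_min, boundary = 0,
                            fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(data = med, ggplot2::aes(xintercept = .data$m),
                        linetype = "dashed") +
    ggplot2::facet_wrap(~state, scales = "free_y") +
    ggplot2::labs(x = "bout duration (min)", y = "count") +
    ggplot2::theme_minimal()
}

#' Plot a grand-average event-related potential
#'
#' @param erp Output of [average_erp()].
#' @param colour Optional column name mapped to colour.
#' @return A ggplot object.
#' @export
plot_erp <- function(erp, colour = NULL) {
  aes <- if (is.null(colour)) {
    ggplot2::aes(x = .data$time_s * 1000, y = .data$mean_lfp)
  } else {
    ggplot2::aes(x = .data$time_s * 1000, y = .data$mean_lfp,
                 colour = .data[[colour]])
  }
  ggplot2::ggplot(erp, aes) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time after stimulus onset (ms)",
                  y = "LFP (a.u.)") +
    ggplot2::theme_minimal()
}
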