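#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Lag profile of a surrogate-screened scan
#'
#' Transfer entropy versus source lag, with the per-lag surrogate 95th
#' percentile drawn as a dashed reference; points above their reference are
#' significant.
#'
#' @param object A `te_scan` from [scan_lags()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.te_scan <- function(object, ...) {
  d <- tibble::as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$tau)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$te_bits)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$te_bits,
                                     shape = .data$significant), size = 2.5) +
    ggplot2::geom_line(ggplot2::aes(y = .data$percentile_95),
                       linetype = "dashed", colour = "grey40") +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1)) +
    ggplot2::labs(x = "source lag (samples)", y = "transfer entropy (bits)",
                  shape = "significant",
                  title = sprintf("Lag scan (%s estimator)",
                                  attr(object, "method", exact = TRUE)))
}

#' Median transfer entropy versus SNR from a sweep
#'
#' One line per estimator and sample size: the median over trials with an
#' interquartile ribbon, the standard way to read a detection benchmark.
#'
#' @param object A `te_sweep` from [run_sweep()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.te_sweep <- function(object, ...) {
  d <- tibble::as_tibble(object) |>
    dplyr::group_by(.data$n, .data$snr_db, .data$method) |>
    dplyr::summarise(
      median = stats::median(.data$te_bits),
      q25 = stats::quantile(.data$te_bits, 0.25),
      q75 = stats::quantile(.data$te_bits, 0.75),
      .groups = "drop"
    )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$snr_db, colour = .data$method,
                                  fill = .data$method)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$q25, ymax = .data$q75),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_line(ggplot2::aes(y = .data$median)) +
    ggplot2::facet_wrap(ggplot2::vars(.data$n), labeller = "label_both") +
    ggplot2::labs(x = "SNR (dB)", y = "transfer entropy (bits)",
                  title = "Transfer entropy vs SNR (median, IQR over trials)")
}

#' Paired pre/post transfer entropies per subject
#'
#' One panel per direction; each line connects a subject's two conditions,
#' mirroring the classic paired-intervention display.
#'
#' @param object A `prepost_study` from [run_prepost_study()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.prepost_study <- function(object, ...) {
  d <- dplyr::filter(object$subjects, .data$significant)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$condition, y = .data$te_bits)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$subject),
                       colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::geom_boxplot(ggplot2::aes(group = .data$condition),
                          width = 0.25, alpha = 0.3,
                          outlier.shape = NA) +
    ggplot2::facet_wrap(ggplot2::vars(.data$direction)) +
    ggplot2::labs(x = NULL, y = "transfer entropy (bits)",
                  title = sprintf("Pre/post coupling (%s estimator)",
                                  object$method))
}
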