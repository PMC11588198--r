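#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a spectrogram
#'
#' @param object A `pcg_spectrogram`.
#' @param ... Unused.
#' @return A ggplot raster of time x frequency.
#' @export
autoplot.pcg_spectrogram <- function(object, ...) {
  df <- expand.grid(frame = seq_len(nrow(object$values)),
                    freq = object$freq)
  df$value <- as.vector(object$values)
  df$time <- (df$frame - 1) * object$frame_step
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$freq,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(
      name = if (object$zscored) "z-score" else "log power") +
    ggplot2::labs(x = "time (s)", y = "frequency (Hz)") +
    ggplot2::theme_minimal()
}

#' Plot per-frame state posteriors
#'
#' @param object A `pcg_posteriors` matrix.
#' @param ... Unused.
#' @return A ggplot of the five posterior traces over time.
#' @export
autoplot.pcg_posteriors <- function(object, ...) {
  df <- tibble::as_tibble(unclass(object)) |>
    dplyr::mutate(time = (dplyr::row_number() - 1) * FRAME_STEP) |>
    tidyr::pivot_longer(-"time", names_to = "state", values_to = "p") |>
    dplyr::mutate(state = state_factor(.data$state))
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$p,
                                   colour = .data$state)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "posterior probability") +
    ggplot2::theme_minimal()
}

#' Plot a decoded segmentation over a recording
#'
#' @param rec A [pcg_recording()].
#' @param segmentation A `pcg_segmentation`, or a tibble of intervals.
#' @return A ggplot of the waveform with state bands.
#' @export
plot_segmentation <- function(rec, segmentation) {
  iv <- if (inherits(segmentation, "pcg_segmentation")) {
    tidy(segmentation)
  } else segmentation
  wave <- tibble::tibble(
    time = (seq_along(rec$samples) - 1) / rec$fs,
    amplitude = rec$samples
  )
  ggplot2::ggplot() +
    ggplot2::geom_rect(
      data = iv,
      ggplot2::aes(xmin = .data$start, xmax = .data$end,
                   ymin = -Inf, ymax = Inf, fill = .data$state),
      alpha = 0.3) +
    ggplot2::geom_line(data = wave,
                       ggplot2::aes(.data$time, .data$amplitude),
                       linewidth = 0.2) +
    ggplot2::labs(x = "time (s)", y = "amplitude") +
    ggplot2::theme_minimal()
}

#' Plot a ROC curve
#'
#' @param object A `roc_result` from [roc_curve()].
#' @param ... Unused.
#' @return A ggplot of sensitivity against 1 - specificity.
#' @export
autoplot.roc_result <- function(object, ...) {
  pts <- object$points[order(1 - object$points$specificity,
                             object$points$sensitivity), ]
  ggplot2::ggplot(pts, ggplot2::aes(1 - .data$specificity,
                                    .data$sensitivity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity",
                  title = sprintf("AUC = %.3f", object$auc)) +
    ggplot2::theme_minimal()
}

#' Reliability diagram for a murmur score
#'
#' @param scores,labels As in [reliability_bins()].
#' @param n_bins Number of bins.
#' @return A ggplot of murmur frequency against mean bin score.
#' @export
plot_reliability <- function(scores, labels, n_bins = 10) {
  bins <- reliability_bins(scores, labels, n_bins)
  ggplot2::ggplot(bins, ggplot2::aes(.data$mean_score, .data$frequency)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$n)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "murmur likelihood", y = "murmur frequency") +
    ggplot2::theme_minimal()
}
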