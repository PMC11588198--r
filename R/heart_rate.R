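#' Probability the signal is not in diastole
#'
#' Collapses a posterior matrix into a periodic scalar series: at each frame
#' the summed probability of S1, systole, S2 and murmur (i.e. one minus the
#' diastole posterior).  This series is a heavily denoised surrogate of the
#' heart-sound envelope and is the input to [estimate_heart_rate()].
#'
#' @param pm A `pcg_posteriors` matrix.
#' @return Numeric vector of length T with values in \[0, 1\].
#' @export
not_diastole_series <- function(pm) {
  stopifnot(ncol(pm) == 5)
  unname(1 - pm[, "diastole"])
}

#' Estimate heart rate by autocorrelation peak search
#'
#' Computes the biased, lag-0-normalised autocorrelation of the mean-removed
#' series and searches for the highest strict local maximum at lags
#' corresponding to 30--180 bpm.  A candidate peak whose doubled lag has a
#' more than 5% higher autocorrelation is rejected as a half-period
#' (S1-to-S2) alias; ties between equal peaks break toward the smaller lag.
#'
#' @param series Numeric series on the 20 ms frame grid, typically from
#'   [not_diastole_series()].
#' @param frame_step Frame step in seconds.
#' @param bpm_range Search window in beats per minute.
#' @return List of class `hr_estimate`: `bpm`, `period_s`, `peak_lag`
#'   (frames), `search_range`.
#' @export
estimate_heart_rate <- function(series, frame_step = FRAME_STEP,
                                bpm_range = c(30, 180)) {
  lag_min <- as.integer(ceiling(60 / bpm_range[2] / frame_step))
  lag_max <- as.integer(floor(60 / bpm_range[1] / frame_step))
  n <- length(series)
  if (n <= lag_max) {
    stop("insufficient duration for HR estimation: need > ", lag_max,
         " frames, got ", n)
  }
  x <- series - mean(series)
  denom <- sum(x^2)
  if (denom == 0) stop("no autocorrelation peak: constant series")
  k_top <- min(2L * lag_max, n - 1L) # extend for the half-period check
  ac <- vapply(seq_len(k_top), function(k) {
    sum(x[seq_len(n - k)] * x[(k + 1):n]) / denom
  }, 0)

  in_win <- seq.int(lag_min, lag_max)
  is_peak <- vapply(in_win, function(k) {
    left <- if (k > 1) ac[k - 1] else 1 # lag 0 value
    k < k_top && ac[k] > left && ac[k] > ac[k + 1]
  }, TRUE)
  peaks <- in_win[is_peak]
  if (length(peaks) == 0) stop("no autocorrelation peak in the search window")
  peaks <- peaks[order(-ac[peaks], peaks)] # by value, ties to smaller lag
  aliased <- vapply(peaks, function(k) {
    2 * k <= k_top && (ac[2 * k] - ac[k]) > 0.05 * abs(ac[k])
  }, TRUE)
  lag <- if (all(aliased)) peaks[1] else peaks[!aliased][1]
  structure(
    list(bpm = 60 / (lag * frame_step), period_s = lag * frame_step,
         peak_lag = lag, search_range = bpm_range),
    class = "hr_estimate"
  )
}

#' @export
print.hr_estimate <- function(x, ...) {
  cat(sprintf("<hr_estimate> %.1f bpm (period %.3f s, lag %d frames)\n",
              x$bpm, x$period_s, x$peak_lag))
  invisible(x)
}

#' Heart rate from a recording via the trained classifier
#'
#' Convenience wrapper: features, posteriors, not-in-diastole series,
#' autocorrelation search.
#'
#' @param rec A [pcg_recording()].
#' @param model A trained `murmur_rnn`.
#' @inheritParams estimate_heart_rate
#' @return An `hr_estimate`.
#' @export
heart_rate <- function(rec, model, bpm_range = c(30, 180)) {
  pm <- predict_posteriors(model, extract_features(rec))
  estimate_heart_rate(not_diastole_series(pm), bpm_range = bpm_range)
}

#' Homomorphic-envelope heart-rate estimate (reference method)
#'
#' Classical envelope-autocorrelation estimator kept as an independent
#' reference: rectified signal, log, first-order low-pass at 8 Hz, exp,
#' downsampled to the 20 ms frame grid, then the same peak search as
#' [estimate_heart_rate()].  Not used in the main analysis path.
#'
#' @param rec A [pcg_recording()].
#' @inheritParams estimate_heart_rate
#' @return An `hr_estimate`.
#' @export
estimate_heart_rate_envelope <- function(rec, bpm_range = c(30, 180)) {
  x <- normalise_amplitude(rec)$samples
  bf <- signal::butter(1, 8 / (rec$fs / 2), type = "low")
  env <- exp(signal::filtfilt(bf, log(pmax(abs(x), 1e-6))))
  step <- round(FRAME_STEP * rec$fs)
  env50 <- env[seq(1, length(env), by = step)]
  estimate_heart_rate(env50, bpm_range = bpm_range)
}
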