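#' Amplitude-normalise a PCG recording
#'
#' Removes the mean and divides by the resulting peak absolute amplitude, so
#' the output has zero mean and `max(abs(samples)) == 1`.  Absolute PCG
#' amplitude carries no diagnostic information (it depends on stethoscope
#' pressure), so all downstream stages assume this normalisation.
#'
#' @param rec A [pcg_recording()].
#' @return The normalised recording.
#' @export
normalise_amplitude <- function(rec) {
  stopifnot(inherits(rec, "pcg_recording"))
  x <- rec$samples - mean(rec$samples)
  peak <- max(abs(x))
  if (peak == 0) stop("degenerate recording: constant signal")
  rec$samples <- x / peak
  rec
}

#' Log-spectrogram features for heart-sound analysis
#'
#' Computes a log power spectrogram with a 50 ms Hann window and a 20 ms
#' step, cropped to 0--800 Hz.  At the native 4000 Hz sampling rate this
#' gives 41 frequency bins spaced 20 Hz apart (the frequency resolution of a
#' 50 ms window) and `T = floor((N - 200) / 80) + 1` frames.  Frames are
#' left-aligned: frame `t` (1-based) covers `[(t-1)*0.02, (t-1)*0.02 + 0.05)`
#' seconds; trailing samples shorter than one window are dropped.
#'
#' Power values are floored at `1e-10` before the log so silent frames do not
#' produce `-Inf`.
#'
#' @param rec A [pcg_recording()], normally after [normalise_amplitude()].
#' @param max_freq Upper band edge in Hz (default 800).
#' @return A `pcg_spectrogram`: list with `values` (T x F matrix, rows =
#'   frames), `freq` (Hz per column), `frame_step`, `frame_len`, `fs` and a
#'   `zscored` flag.
#' @export
log_spectrogram <- function(rec, max_freq = 800) {
  stopifnot(inherits(rec, "pcg_recording"))
  fs <- rec$fs
  win <- round(FRAME_LEN * fs)   # 200 samples at 4 kHz
  step <- round(FRAME_STEP * fs) # 80 samples
  n <- length(rec$samples)
  if (n < win) stop("recording too short: need at least ", win, " samples")
  n_frames <- (n - win) %/% step + 1L
  hann <- 0.5 * (1 - cos(2 * pi * (0:(win - 1)) / win))
  idx <- outer(0:(win - 1), (0:(n_frames - 1)) * step, `+`) + 1L
  frames <- matrix(rec$samples[idx], nrow = win) * hann
  spec <- stats::mvfft(frames)
  freq <- (0:(win %/% 2)) * (fs / win)
  keep <- freq <= max_freq + 1e-9
  power <- Mod(spec[seq_along(freq)[keep], , drop = FALSE])^2
  vals <- t(log(pmax(power, 1e-10)))
  structure(
    list(values = vals, freq = freq[keep], frame_step = FRAME_STEP,
         frame_len = FRAME_LEN, fs = fs, zscored = FALSE),
    class = "pcg_spectrogram"
  )
}

#' @export
print.pcg_spectrogram <- function(x, ...) {
  cat(sprintf("<pcg_spectrogram> %d frames x %d bins (0-%g Hz, %s)\n",
              nrow(x$values), ncol(x$values), max(x$freq),
              if (x$zscored) "z-scored" else "raw log-power"))
  invisible(x)
}

#' Z-score each frequency row of a spectrogram
#'
#' Each frequency bin is centred and rescaled across time so that quiet
#' broadband structure (murmurs) is placed on the same footing as the strong
#' S1/S2 transients.  By default the conventional z-score (divide by the
#' standard deviation) is used; `scale = "var"` divides by the variance
#' instead.  Constant rows map to all-zero rows.
#'
#' @param sf A `pcg_spectrogram` from [log_spectrogram()].
#' @param scale `"sd"` (default) or `"var"`.
#' @return The spectrogram with z-scored values.
#' @export
zscore_rows <- function(sf, scale = c("sd", "var")) {
  stopifnot(inherits(sf, "pcg_spectrogram"))
  scale <- match.arg(scale)
  v <- sf$values
  if (nrow(v) < 2) stop("need at least 2 frames to z-score")
  mu <- colMeans(v)
  centred <- sweep(v, 2, mu)
  s <- sqrt(colMeans(centred^2)) # population scaling: a 2-point row maps to +/-1
  if (scale == "var") s <- s^2
  s[s == 0] <- Inf # constant rows -> zeros
  sf$values <- sweep(centred, 2, s, `/`)
  sf$zscored <- TRUE
  sf
}

#' Full feature-extraction front end
#'
#' Convenience composition `normalise_amplitude |> log_spectrogram |>
#' zscore_rows` — the exact input representation the frame classifier is
#' trained on.
#'
#' @inheritParams log_spectrogram
#' @inheritParams zscore_rows
#' @return A z-scored `pcg_spectrogram`.
#' @export
extract_features <- function(rec, max_freq = 800, scale = "sd") {
  zscore_rows(log_spectrogram(normalise_amplitude(rec), max_freq = max_freq),
              scale = scale)
}

#' Number of spectrogram frames for a recording length
#'
#' @param n_samples Recording length in samples.
#' @param fs Sampling rate (Hz).
#' @return Integer frame count `floor((N - win) / step) + 1`.
#' @export
n_frames_for <- function(n_samples, fs = 4000) {
  win <- round(FRAME_LEN * fs); step <- round(FRAME_STEP * fs)
  as.integer((n_samples - win) %/% step + 1L)
}
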