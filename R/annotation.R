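#' Rasterise segmentation intervals onto the frame grid
#'
#' Frame `t` (1-based) takes the state of the interval containing its centre
#' time `(t-1)*step + win/2`.  Frame centres falling outside every interval
#' take the nearest interval's state (with a warning): recordings are
#' annotated end-to-end, so this only happens at the edges.
#'
#' @param intervals Tibble of `start`, `end`, `state` (see
#'   [read_segmentation()]).
#' @param n_frames Number of frames `T` in the paired feature matrix.
#' @return A `frame_labels` object: factor of length `T` over the five
#'   states, with a `frame_step` attribute.
#' @export
intervals_to_frames <- function(intervals, n_frames) {
  stopifnot(nrow(intervals) >= 1, n_frames >= 1)
  iv <- intervals[intervals$end > intervals$start, , drop = FALSE] # drop empty
  centres <- (seq_len(n_frames) - 1) * FRAME_STEP + FRAME_LEN / 2
  # half-open [start, end): index of containing interval
  hit <- findInterval(centres, iv$start)
  state <- rep(NA_character_, n_frames)
  inside <- hit >= 1 & centres < iv$end[pmax(hit, 1)]
  state[inside] <- as.character(iv$state[hit[inside]])
  if (any(!inside)) {
    # nearest interval by distance to its span
    for (t in which(!inside)) {
      d <- pmax(iv$start - centres[t], centres[t] - iv$end, 0)
      state[t] <- as.character(iv$state[which.min(d)])
    }
    warning(sum(!inside), " frame centre(s) outside all intervals; ",
            "used nearest interval's state")
  }
  structure(state_factor(state), frame_step = FRAME_STEP, class = c("frame_labels", "factor"))
}

#' Expand systole frames into murmur frames from the murmur-timing label
#'
#' Clinical annotations localise murmurs only by their timing within systole.
#' For each maximal run of `L` systole frames: an early-systolic murmur
#' claims the first `ceil(L/2)` frames, a mid-systolic murmur the middle
#' `ceil(L/2)` frames (starting at offset `floor(L/4)`), and a holosystolic
#' murmur all `L` frames; `timing = "none"` leaves the labels unchanged.
#' S1, S2 and diastole frames are never altered, and the operation is
#' idempotent (murmur frames are not re-expanded).
#'
#' @param labels A `frame_labels` object.
#' @param timing One of `"none"`, `"early-systolic"`, `"mid-systolic"`,
#'   `"holosystolic"`.
#' @return The expanded `frame_labels`.
#' @export
expand_murmur <- function(labels, timing = c("none", "early-systolic",
                                             "mid-systolic", "holosystolic")) {
  timing <- match.arg(timing)
  if (timing == "none") return(labels)
  x <- as.character(labels)
  # a systolic period is a maximal run of systole-or-murmur frames, so the
  # operation is idempotent: re-expanding an expanded sequence changes nothing
  r <- rle(x %in% c("systole", "murmur"))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  for (i in which(r$values)) {
    L <- r$lengths[i]
    run <- starts[i]:ends[i]
    mur <- switch(timing,
      "holosystolic" = run,
      "early-systolic" = run[seq_len(ceiling(L / 2))],
      "mid-systolic" = run[floor(L / 4) + seq_len(ceiling(L / 2))]
    )
    x[run] <- "systole"
    x[mur] <- "murmur"
  }
  structure(state_factor(x), frame_step = attr(labels, "frame_step"),
            class = c("frame_labels", "factor"))
}

#' Convert a frame-state sequence back to intervals
#'
#' Inverse of rasterisation: maximal runs of equal state become half-open
#' intervals on the frame-step grid (frame `t` contributes
#' `[(t-1)*step, t*step)`).
#'
#' @param states Factor or character vector of per-frame states.
#' @return Tibble with `start`, `end`, `state`.
#' @export
frames_to_intervals <- function(states) {
  x <- as.character(states)
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  tibble::tibble(
    start = (starts - 1) * FRAME_STEP,
    end = ends * FRAME_STEP,
    state = state_factor(r$values)
  )
}
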