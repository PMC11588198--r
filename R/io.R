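#' PCG recording object
#'
#' Lightweight container for a mono phonocardiogram: a numeric sample vector
#' plus its sampling rate and provenance.  Recordings conforming to the
#' electronic-stethoscope datasets this package targets are sampled at
#' 4000 Hz.
#'
#' @param samples Numeric vector of dimensionless amplitudes.
#' @param fs Sampling rate in Hz.
#' @param recording_id Opaque identifier string.
#' @param site Auscultation site, one of `"AV"`, `"PV"`, `"TV"`, `"MV"` or
#'   `"other"`.
#' @return An object of class `pcg_recording`.
#' @export
pcg_recording <- function(samples, fs = 4000, recording_id = "rec", site = "other") {
  stopifnot(is.numeric(samples), length(samples) >= 1, fs > 0)
  site <- match.arg(site, c(PCG_SITES, "other"))
  structure(
    list(samples = as.numeric(samples), fs = fs,
         recording_id = recording_id, site = site),
    class = "pcg_recording"
  )
}

#' @export
print.pcg_recording <- function(x, ...) {
  cat(sprintf("<pcg_recording '%s'> %d samples @ %g Hz (%.2f s), site %s\n",
              x$recording_id, length(x$samples), x$fs,
              length(x$samples) / x$fs, x$site))
  invisible(x)
}

#' Read a mono PCM WAV file as a PCG recording
#'
#' Supports uncompressed 8/16/32-bit integer PCM and 32/64-bit float WAV.
#' Samples are returned as floats scaled to roughly \[-1, 1\] for integer
#' encodings.
#'
#' @param path Path to a WAV file.
#' @param recording_id,site Provenance attached to the returned object;
#'   `recording_id` defaults to the file name.
#' @return A [pcg_recording()].
#' @export
read_recording <- function(path, recording_id = NULL, site = "other") {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("unreadable WAV header (missing RIFF): ", path)
  readBin(con, "integer", 1, 4, endian = "little")
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("unreadable WAV header (missing WAVE): ", path)

  fmt <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) stop("no data chunk found in ", path)
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      raw <- readBin(con, "raw", sz)
      fmt <- list(
        audio_format = readBin(raw[1:2], "integer", 1, 2, endian = "little"),
        channels     = readBin(raw[3:4], "integer", 1, 2, endian = "little"),
        fs           = readBin(raw[5:8], "integer", 1, 4, endian = "little"),
        bits         = readBin(raw[15:16], "integer", 1, 2, endian = "little")
      )
    } else if (identical(id, "data")) {
      if (is.null(fmt)) stop("data chunk before fmt chunk in ", path)
      if (fmt$channels != 1) stop("expected mono WAV, got ", fmt$channels, " channels: ", path)
      n <- sz %/% (fmt$bits %/% 8)
      samples <- switch(
        as.character(fmt$audio_format),
        "1" = { # integer PCM
          if (fmt$bits == 16) {
            readBin(con, "integer", n, 2, signed = TRUE, endian = "little") / 32768
          } else if (fmt$bits == 32) {
            readBin(con, "integer", n, 4, endian = "little") / 2147483648
          } else if (fmt$bits == 8) {
            (readBin(con, "integer", n, 1, signed = FALSE) - 128) / 128
          } else stop("unsupported PCM bit depth: ", fmt$bits)
        },
        "3" = readBin(con, "double", n, fmt$bits %/% 8, endian = "little"),
        stop("unsupported WAV encoding (format tag ", fmt$audio_format, ")")
      )
      return(pcg_recording(samples, fs = fmt$fs,
                           recording_id = recording_id %||%
                             sub("\\.wav$", "", basename(path), ignore.case = TRUE),
                           site = site))
    } else {
      seek(con, sz + sz %% 2, origin = "current") # chunks are word-aligned
    }
  }
}

#' Write a PCG recording to a 16-bit PCM mono WAV file
#'
#' Amplitudes outside \[-1, 1\] are clipped.
#'
#' @param rec A [pcg_recording()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "pcg_recording"))
  x <- pmin(1, pmax(-1, rec$samples))
  pcm <- as.integer(pmin(32767, round(x * 32768))) # symmetric with read scale
  n_bytes <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(1L, con, 2, endian = "little")                       # PCM
  writeBin(1L, con, 2, endian = "little")                       # mono
  writeBin(as.integer(rec$fs), con, 4, endian = "little")
  writeBin(as.integer(rec$fs * 2), con, 4, endian = "little")   # byte rate
  writeBin(2L, con, 2, endian = "little")                       # block align
  writeBin(16L, con, 2, endian = "little")                      # bits
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, 4, endian = "little")
  writeBin(pcm, con, 2, endian = "little")
  invisible(path)
}

# numeric state codes used in segmentation files; 5 (murmur) extends the
# common 4-code scheme so expanded ground truth can round-trip
STATE_CODES <- setNames(1:5, PCG_STATES)

#' Read a segmentation interval file
#'
#' Parses the three-column whitespace-separated dialect: start seconds, end
#' seconds, integer state code (1 = S1, 2 = systole, 3 = S2, 4 = diastole,
#' 5 = murmur).  Intervals are half-open `[start, end)` and must be ordered
#' and non-overlapping.
#'
#' @param path Path to the interval file.
#' @return A tibble with columns `start`, `end` (seconds) and `state`
#'   (factor over the five states).
#' @export
read_segmentation <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(tibble::tibble(start = numeric(), end = numeric(),
                          state = state_factor(character())))
  }
  parts <- strsplit(trimws(lines), "\\s+")
  bad <- which(lengths(parts) != 3)
  if (length(bad)) stop("row ", bad[1], ": expected 3 columns in ", path)
  m <- matrix(unlist(parts), ncol = 3, byrow = TRUE)
  start <- as.numeric(m[, 1]); end <- as.numeric(m[, 2]); code <- as.integer(m[, 3])
  if (anyNA(start) || anyNA(end) || anyNA(code)) {
    stop("row ", which(is.na(start) | is.na(end) | is.na(code))[1],
         ": non-numeric field in ", path)
  }
  if (any(code < 1 | code > 5)) {
    stop("row ", which(code < 1 | code > 5)[1], ": unknown state code in ", path)
  }
  if (any(start >= end)) stop("row ", which(start >= end)[1], ": start >= end in ", path)
  if (length(start) > 1) {
    ooo <- which(diff(start) < 0)
    if (length(ooo)) stop("row ", ooo[1] + 1, ": rows out of order in ", path)
    ov <- which(start[-1] < end[-length(end)] - 1e-9)
    if (length(ov)) stop("row ", ov[1] + 1, ": overlapping intervals in ", path)
  }
  tibble::tibble(start = start, end = end,
                 state = state_factor(PCG_STATES[code]))
}

#' Write segmentation intervals
#'
#' Inverse of [read_segmentation()]; times are written with six decimals so
#' read/write round-trips are exact at that precision.
#'
#' @param intervals Tibble with `start`, `end`, `state` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_segmentation <- function(intervals, path) {
  code <- STATE_CODES[as.character(intervals$state)]
  writeLines(sprintf("%.6f\t%.6f\t%d", intervals$start, intervals$end, code), path)
  invisible(path)
}

#' Read a patient metadata block
#'
#' Parses the flat `key: value` per-line format written by
#' [simulate_cohort()].  Recognised keys: `patient_id`, `age_group`,
#' `pregnant`, `murmur`, `murmur_timing`, `outcome`, `recordings`
#' (comma-separated `recording_id=site` pairs).  Unknown keys are ignored
#' with a warning.
#'
#' @param path Path to the metadata text file.
#' @return A one-row tibble with a list-column `recordings` (tibble of
#'   `recording_id`, `site`).
#' @export
read_patient <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  kv <- regmatches(lines, regexec("^([^:]+):\\s*(.*)$", lines))
  keys <- vapply(kv, function(x) trimws(x[2]), "")
  vals <- vapply(kv, function(x) trimws(x[3]), "")
  known <- c("patient_id", "age_group", "pregnant", "murmur", "murmur_timing",
             "outcome", "recordings")
  if (any(!keys %in% known)) {
    warning("ignoring unknown metadata keys: ",
            paste(setdiff(keys, known), collapse = ", "))
  }
  get <- function(k, default = NA_character_) if (k %in% keys) vals[keys == k][1] else default
  recs <- get("recordings", "")
  rec_tbl <- if (nzchar(recs)) {
    pairs <- strsplit(strsplit(recs, ",")[[1]], "=")
    tibble::tibble(recording_id = vapply(pairs, `[`, "", 1),
                   site = vapply(pairs, `[`, "", 2))
  } else {
    tibble::tibble(recording_id = character(), site = character())
  }
  tibble::tibble(
    patient_id = get("patient_id", basename(path)),
    age_group = get("age_group"),
    pregnant = tolower(get("pregnant", "false")) %in% c("true", "1", "yes"),
    murmur = get("murmur", "absent"),
    murmur_timing = get("murmur_timing", "none"),
    outcome = get("outcome"),
    recordings = list(rec_tbl)
  )
}

#' Write per-recording results as JSON lines
#'
#' One JSON object per row of `results`; list-columns are unboxed where
#' length-1.  The inverse is [read_results()].
#'
#' @param results A data frame, typically from [detect_murmur()] /
#'   [segment_cohort()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(results))) {
    row <- as.list(results[i, , drop = FALSE])
    row <- lapply(row, function(x) if (is.list(x)) x[[1]] else x)
    row <- row[!vapply(row, function(x) is.data.frame(x) || is.null(x), TRUE)]
    writeLines(jsonlite::toJSON(row, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' Read a JSON-lines results file
#'
#' @param path Path written by [write_results()].
#' @return A tibble with one row per line.
#' @export
read_results <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  rows <- lapply(lines, function(l) {
    x <- jsonlite::fromJSON(l)
    tibble::as_tibble(x[lengths(x) == 1])
  })
  dplyr::bind_rows(rows)
}
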