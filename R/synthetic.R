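#' Configuration for the synthetic PCG generator
#'
#' The generator emulates the signal structure the analysis pipeline
#' assumes: periodic S1 (~100 ms) and shorter S2 (~80 ms) transient bursts
#' of low-frequency tonal energy, an optional systolic murmur rendered as
#' 100--400 Hz band-passed noise occupying the configured portion of
#' systole, paediatric heart rates up to 180 bpm with +/-5% cycle jitter,
#' and additive broadband noise.
#'
#' @param fs Sampling rate, Hz.
#' @param heart_rate_bpm A single rate or a `c(lo, hi)` range to draw from.
#' @param s1_dur,s2_dur S1/S2 burst durations, seconds.
#' @param systole_frac Systolic interval as a fraction of the cycle
#'   (must lie in (0.2, 0.5)).
#' @param murmur One of `"none"`, `"holo"`, `"early"`, `"mid"`.
#' @param murmur_snr_db Murmur RMS relative to the S1 burst RMS, dB.
#' @param noise_snr_db Signal-to-broadband-noise ratio, dB.
#' @param duration_s Recording length, seconds.
#' @param seed Optional integer seed (recordings are bit-identical for a
#'   fixed seed).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(fs = 4000, heart_rate_bpm = c(60, 180), s1_dur = 0.10,
                       s2_dur = 0.08, systole_frac = 0.30,
                       murmur = c("none", "holo", "early", "mid"),
                       murmur_snr_db = -6, noise_snr_db = 20,
                       duration_s = 10, seed = NULL) {
  murmur <- match.arg(murmur)
  stopifnot(fs > 0, s1_dur > 0, s2_dur > 0,
            systole_frac > 0.2, systole_frac < 0.5, duration_s > 0)
  structure(as.list(environment()), class = "sim_config")
}

# Gaussian-windowed tone burst
burst <- function(fs, dur, freq, phase = 0) {
  t <- seq(0, dur, by = 1 / fs)[-1]
  env <- exp(-0.5 * ((t - dur / 2) / (dur / 4))^2)
  env * sin(2 * pi * freq * t + phase)
}

#' Simulate one labelled PCG recording
#'
#' Builds a waveform cycle by cycle (S1 burst, optional murmur noise over
#' the configured part of systole, S2 burst, silent diastole) plus white
#' noise, and returns exact ground-truth intervals — five-state when a
#' murmur is present, with the murmur sub-interval replacing the murmured
#' part of systole.
#'
#' @param cfg A [sim_config()].
#' @param recording_id,site Provenance for the returned recording.
#' @return List: `recording` (a [pcg_recording()]), `intervals` (tibble),
#'   `bpm` (the realised mean rate), `config`.
#' @export
simulate_pcg <- function(cfg = sim_config(), recording_id = "sim", site = "other") {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  fs <- cfg$fs
  bpm <- if (length(cfg$heart_rate_bpm) == 2) {
    runif(1, cfg$heart_rate_bpm[1], cfg$heart_rate_bpm[2])
  } else cfg$heart_rate_bpm
  n <- round(cfg$duration_s * fs)
  x <- numeric(n)
  f1 <- runif(1, 60, 150)  # S1 tone frequency
  f2 <- runif(1, 80, 200)  # S2 tone frequency

  iv <- list()
  add_iv <- function(s, e, state) {
    if (e > s) iv[[length(iv) + 1]] <<- tibble::tibble(start = s, end = e,
                                                       state = state)
  }
  place <- function(seg, at) { # add burst samples at time `at` seconds
    i0 <- round(at * fs) + 1
    idx <- i0:min(i0 + length(seg) - 1, n)
    if (length(idx) > 0 && idx[1] <= n) {
      x[idx] <<- x[idx] + seg[seq_along(idx)]
    }
  }

  mur_spans <- list() # murmur noise spans (start, end seconds)
  t0 <- 0
  while (t0 < cfg$duration_s) {
    cyc <- (60 / bpm) * (1 + runif(1, -0.05, 0.05))
    sysd <- cfg$systole_frac * cyc
    diad <- cyc - cfg$s1_dur - sysd - cfg$s2_dur
    if (diad <= 0.01) stop("infeasible durations: no diastole left in cycle")
    s1_end <- t0 + cfg$s1_dur
    sys_end <- s1_end + sysd
    s2_end <- sys_end + cfg$s2_dur
    place(burst(fs, cfg$s1_dur, f1, runif(1, 0, 2 * pi)), t0)
    place(0.8 * burst(fs, cfg$s2_dur, f2, runif(1, 0, 2 * pi)), sys_end)
    add_iv(t0, s1_end, "S1")
    if (cfg$murmur == "none") {
      add_iv(s1_end, sys_end, "systole")
    } else {
      mur <- switch(cfg$murmur,
        holo = c(s1_end, sys_end),
        early = c(s1_end, s1_end + sysd / 2),
        mid = c(s1_end + sysd / 4, s1_end + 3 * sysd / 4)
      )
      add_iv(s1_end, mur[1], "systole")
      add_iv(mur[1], mur[2], "murmur")
      add_iv(mur[2], sys_end, "systole")
      mur_spans[[length(mur_spans) + 1]] <- mur
    }
    add_iv(sys_end, s2_end, "S2")
    add_iv(s2_end, t0 + cyc, "diastole")
    t0 <- t0 + cyc
  }

  s1_rms <- sqrt(mean(burst(fs, cfg$s1_dur, f1)^2))
  if (length(mur_spans) > 0) {
    bf <- signal::butter(4, c(100, 400) / (fs / 2), type = "pass")
    mnoise <- signal::filtfilt(bf, rnorm(n))
    mnoise <- mnoise / sqrt(mean(mnoise^2)) *
      s1_rms * 10^(cfg$murmur_snr_db / 20)
    ramp <- 0.010 # 10 ms raised-cosine edges
    for (sp in mur_spans) {
      i0 <- round(sp[1] * fs) + 1
      i1 <- min(round(sp[2] * fs), n)
      if (i1 <= i0) next
      m <- i1 - i0 + 1
      w <- rep(1, m)
      re <- min(round(ramp * fs), floor(m / 2))
      if (re > 0) {
        edge <- 0.5 * (1 - cos(pi * seq_len(re) / re))
        w[seq_len(re)] <- edge
        w[m + 1 - seq_len(re)] <- rev(edge)
      }
      x[i0:i1] <- x[i0:i1] + mnoise[i0:i1] * w
    }
  }

  sig_rms <- sqrt(mean(x^2))
  x <- x + rnorm(n, sd = sig_rms * 10^(-cfg$noise_snr_db / 20))

  intervals <- dplyr::bind_rows(iv) |>
    dplyr::filter(.data$start < cfg$duration_s) |>
    dplyr::mutate(end = pmin(.data$end, cfg$duration_s),
                  state = state_factor(.data$state))
  list(
    recording = pcg_recording(x / max(abs(x)) * 0.9, fs = fs,
                              recording_id = recording_id, site = site),
    intervals = intervals,
    bpm = bpm,
    config = cfg
  )
}

# murmur grade tiers: dB relative to S1 burst RMS
MURMUR_GRADE_DB <- c(quiet = -12, moderate = -6, loud = 0)

#' Simulate a labelled patient cohort
#'
#' Draws patients with 1--4 auscultation-site recordings sharing the
#' patient's heart rate, a murmur with probability `murmur_prevalence`
#' (timing and grade shared across that patient's sites), a small fraction
#' of poor-quality patients labelled `unknown` (rendered with heavy
#' broadband noise), and a clinical outcome drawn from a logistic model in
#' the murmur grade — so some abnormal patients have no audible murmur.
#'
#' @param n_patients Number of patients (>= 2).
#' @param murmur_prevalence Probability a patient has a murmur.
#' @param unknown_rate Fraction of patients with unclassifiable recordings.
#' @param duration_s Recording length per site.
#' @param outcome_coef `c(intercept, slope)` of the logistic outcome model
#'   on murmur grade (0 = none .. 3 = loud).
#' @param seed Integer seed.
#' @param dir Optional directory: when given, WAV + segmentation TSV +
#'   metadata files are written there via the io module.
#' @return Tibble with one row per recording: `patient_id`, `age_group`,
#'   `pregnant`, `murmur_label`, `murmur_timing`, `grade`, `outcome`,
#'   `bpm`, `site`, `recording_id`, and list-columns `recording`,
#'   `intervals`.
#' @export
simulate_cohort <- function(n_patients, murmur_prevalence = 0.3,
                            unknown_rate = 0.05, duration_s = 10,
                            outcome_coef = c(-1.5, 0.9), seed = 1L,
                            dir = NULL) {
  stopifnot(n_patients >= 2, murmur_prevalence > 0, murmur_prevalence < 1)
  set.seed(seed)
  rows <- list()
  for (i in seq_len(n_patients)) {
    pid <- sprintf("P%04d", i)
    has_murmur <- runif(1) < murmur_prevalence
    unknown <- runif(1) < unknown_rate
    timing <- if (has_murmur) sample(c("early", "mid", "holo"), 1) else "none"
    grade <- if (has_murmur) sample(names(MURMUR_GRADE_DB), 1) else "none"
    grade_num <- if (has_murmur) match(grade, names(MURMUR_GRADE_DB)) else 0
    bpm <- runif(1, 60, 174) # paediatric range, inside the 30-180 search cap
    age_group <- sample(AGE_GROUPS, 1, prob = c(0.1, 0.2, 0.4, 0.25, 0.05))
    pregnant <- age_group %in% c("adolescent", "young-adult") && runif(1) < 0.1
    outcome <- if (runif(1) < stats::plogis(outcome_coef[1] +
                                            outcome_coef[2] * grade_num)) {
      "abnormal"
    } else "normal"
    n_sites <- sample(1:4, 1)
    sites <- sample(PCG_SITES, n_sites)
    for (s in sites) {
      rid <- paste0(pid, "_", s)
      cfg <- sim_config(
        heart_rate_bpm = min(178, bpm + runif(1, -3, 3)),
        murmur = if (has_murmur) timing else "none",
        murmur_snr_db = if (has_murmur) MURMUR_GRADE_DB[[grade]] else -6,
        noise_snr_db = if (unknown) runif(1, -6, -2) else runif(1, 15, 25),
        duration_s = duration_s
      )
      sim <- simulate_pcg(cfg, recording_id = rid, site = s)
      rows[[length(rows) + 1]] <- tibble::tibble(
        patient_id = pid, age_group = age_group, pregnant = pregnant,
        murmur_label = if (unknown) "unknown"
                       else if (has_murmur) "present" else "absent",
        murmur_timing = switch(timing, none = "none",
                               early = "early-systolic",
                               mid = "mid-systolic", holo = "holosystolic"),
        grade = grade, outcome = outcome, bpm = sim$bpm, site = s,
        recording_id = rid, recording = list(sim$recording),
        intervals = list(sim$intervals)
      )
    }
  }
  manifest <- dplyr::bind_rows(rows)
  if (!is.null(dir)) write_cohort(manifest, dir)
  manifest
}

#' Write a simulated cohort to disk in the standard formats
#'
#' One WAV + segmentation TSV per recording and one `key: value` metadata
#' block per patient, all readable back through the io module.
#'
#' @param manifest Tibble from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(manifest, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(nrow(manifest))) {
    rid <- manifest$recording_id[i]
    write_recording(manifest$recording[[i]], file.path(dir, paste0(rid, ".wav")))
    write_segmentation(manifest$intervals[[i]], file.path(dir, paste0(rid, ".tsv")))
  }
  for (pid in unique(manifest$patient_id)) {
    rows <- manifest[manifest$patient_id == pid, ]
    writeLines(c(
      paste0("patient_id: ", pid),
      paste0("age_group: ", rows$age_group[1]),
      paste0("pregnant: ", tolower(rows$pregnant[1])),
      paste0("murmur: ", rows$murmur_label[1]),
      paste0("murmur_timing: ", rows$murmur_timing[1]),
      paste0("outcome: ", rows$outcome[1]),
      paste0("recordings: ",
             paste(paste0(rows$recording_id, "=", rows$site), collapse = ","))
    ), file.path(dir, paste0(pid, ".txt")))
  }
  utils::write.csv(manifest[, c("patient_id", "recording_id", "site",
                                "murmur_label", "murmur_timing", "grade",
                                "outcome", "bpm")],
                   file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(dir)
}

#' Frame-level training data from a cohort manifest
#'
#' Extracts z-scored spectrogram features and rasterised five-state frame
#' labels for every recording.
#'
#' @param manifest Tibble from [simulate_cohort()].
#' @return List with `features` (list of `pcg_spectrogram`) and `labels`
#'   (list of `frame_labels`).
#' @export
cohort_frame_data <- function(manifest) {
  features <- lapply(manifest$recording, extract_features)
  labels <- lapply(seq_len(nrow(manifest)), function(i) {
    intervals_to_frames(manifest$intervals[[i]],
                        nrow(features[[i]]$values))
  })
  list(features = features, labels = labels)
}

#' Simulate a feature-level outcome cohort
#'
#' Generates per-patient outcome feature vectors directly (no audio): each
#' patient has 1--4 sites with murmur-likelihood values drawn around a
#' grade-dependent mean, and the clinical outcome is Bernoulli with
#' logistic probability in the patient's best (maximum) site murmur
#' likelihood — the planted relationship the outcome classifier should
#' recover.  Used to exercise the outcome model without running the full
#' audio pipeline.
#'
#' @param n_patients Cohort size.
#' @param murmur_prevalence Probability of a murmur (grade > 0).
#' @param seed Integer seed.
#' @return Tibble in the layout of [build_outcome_features()] including
#'   `outcome`.
#' @export
simulate_outcome_cohort <- function(n_patients, murmur_prevalence = 0.35,
                                    seed = 1L) {
  set.seed(seed)
  cmn_mu <- c(-0.06, 0.03, 0.09, 0.16) # grade 0..3 mean C(M-N)
  rows <- lapply(seq_len(n_patients), function(i) {
    grade <- if (runif(1) < murmur_prevalence) sample(1:3, 1) else 0
    n_sites <- sample(1:4, 1)
    sites <- sample(PCG_SITES, n_sites)
    cmn <- setNames(rep(NA_real_, 4), PCG_SITES)
    q <- setNames(rep(NA_real_, 4), PCG_SITES)
    cmn[sites] <- rnorm(n_sites, cmn_mu[grade + 1], 0.03)
    q[sites] <- pmin(0.99, pmax(0.3, rnorm(n_sites, 0.85, 0.08)))
    max_cmn <- max(cmn, na.rm = TRUE)
    p_abn <- stats::plogis(-2.5 + 40 * max_cmn)
    out <- tibble::tibble(patient_id = sprintf("S%04d", i))
    for (s in PCG_SITES) out[[paste0("cmn_", s)]] <- cmn[[s]]
    for (s in PCG_SITES) out[[paste0("q_", s)]] <- q[[s]]
    out$age_group <- sample.int(5, 1)
    out$pregnant <- as.integer(runif(1) < 0.05)
    out$n_recordings <- n_sites
    out$outcome <- if (runif(1) < p_abn) "abnormal" else "normal"
    out
  })
  dplyr::bind_rows(rows)
}
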