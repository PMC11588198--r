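#' Greedy (unconstrained) frame-wise segmentation
#'
#' Picks the state with the maximum posterior at each frame independently;
#' ties break toward the earlier state in the fixed order.  Included as the
#' baseline the duration-constrained decoders improve upon: it enforces no
#' transition structure, so physically impossible sequences (e.g. S2 to
#' systole) can occur.
#'
#' @param pm A `pcg_posteriors` matrix.
#' @return Factor of per-frame states.
#' @export
greedy_segmentation <- function(pm) {
  state_factor(PCG_STATES[max.col(unclass(pm), ties.method = "first")])
}

# cycle-share duration defaults (seconds / fractions); config-exposed via
# build_model_bank arguments
DUR_S1 <- 0.122
DUR_S2 <- 0.092
SYS_DIA_RATIO <- c(1, 1.7)
DUR_SD_FRAC <- 0.25

#' Build the bank of four duration-explicit HSMMs
#'
#' The four models share heart-rate-scaled Gaussian duration distributions
#' but differ in decode topology and in which posterior column each decode
#' state observes:
#' * `w1` — normal signal: cycle S1-systole-S2-diastole; the murmur
#'   posterior is discarded and the remaining four columns renormalised.
#' * `w2` — holosystolic murmur: same 4-state cycle but systole observes the
#'   murmur posterior.
#' * `w3` — early-systolic murmur: 5-state cycle
#'   S1-murmur-systole-S2-diastole.
#' * `w4` — mid-systolic murmur: 6-state cycle
#'   S1-sysA-murmur-sysB-S2-diastole, where sysA/sysB both observe the
#'   systole posterior (a single systole state cannot hold a mid-systolic
#'   murmur in a cyclic chain).
#'
#' S1 and S2 duration means are fixed; the remaining cycle time is split
#' systole:diastole = 1:1.7, murmur sub-states split the systolic share per
#' the 50% murmur-labelling rule, and every model's duration means sum to
#' one full cycle `60/bpm` seconds.  Duration sd is 25% of the mean.
#'
#' @param hr An `hr_estimate` (or a bare bpm value).
#' @param s1_dur,s2_dur S1/S2 duration means in seconds.
#' @param sys_dia_ratio Length-2 vector splitting the non-S1/S2 cycle time.
#' @param sd_frac Duration sd as a fraction of the mean.
#' @return Named list of four `hsmm_model` objects.
#' @export
build_model_bank <- function(hr, s1_dur = DUR_S1, s2_dur = DUR_S2,
                             sys_dia_ratio = SYS_DIA_RATIO,
                             sd_frac = DUR_SD_FRAC) {
  bpm <- if (inherits(hr, "hr_estimate")) hr$bpm else hr
  cycle <- 60 / bpm
  rem <- cycle - s1_dur - s2_dur
  if (rem <= 0) stop("heart rate too high for the fixed S1/S2 durations")
  sys <- rem * sys_dia_ratio[1] / sum(sys_dia_ratio)
  dia <- rem * sys_dia_ratio[2] / sum(sys_dia_ratio)

  mk <- function(id, states, means, obs, timing) {
    structure(
      list(model_id = id, states = states,
           duration_mean = setNames(means, states),
           duration_sd = setNames(pmax(means * sd_frac, 1e-6), states),
           obs = obs, timing = timing, bpm = bpm),
      class = "hsmm_model"
    )
  }
  list(
    w1 = mk("w1", c("S1", "systole", "S2", "diastole"),
            c(s1_dur, sys, s2_dur, dia),
            obs = "renorm4", timing = "none"),
    w2 = mk("w2", c("S1", "systole", "S2", "diastole"),
            c(s1_dur, sys, s2_dur, dia),
            obs = c(S1 = "S1", systole = "murmur", S2 = "S2",
                    diastole = "diastole"),
            timing = "holosystolic"),
    w3 = mk("w3", c("S1", "murmur", "systole", "S2", "diastole"),
            c(s1_dur, sys / 2, sys / 2, s2_dur, dia),
            obs = c(S1 = "S1", murmur = "murmur", systole = "systole",
                    S2 = "S2", diastole = "diastole"),
            timing = "early-systolic"),
    w4 = mk("w4", c("S1", "sysA", "murmur", "sysB", "S2", "diastole"),
            c(s1_dur, sys / 4, sys / 2, sys / 4, s2_dur, dia),
            obs = c(S1 = "S1", sysA = "systole", murmur = "murmur",
                    sysB = "systole", S2 = "S2", diastole = "diastole"),
            timing = "mid-systolic")
  )
}

#' @export
print.hsmm_model <- function(x, ...) {
  cat(sprintf("<hsmm_model %s> cycle %s (%.1f bpm)\n", x$model_id,
              paste(x$states, collapse = "->"), x$bpm))
  invisible(x)
}

#' Observation probabilities for a model's decode states
#'
#' Maps the 5-column posterior matrix onto a model's decode states.  For
#' `w1` the murmur column is dropped and the remaining four renormalised per
#' frame; murmur models read raw posterior columns (sysA/sysB read systole,
#' `w2`'s systole reads murmur).
#'
#' @param pm A `pcg_posteriors` matrix.
#' @param model An `hsmm_model`.
#' @return T x n_states matrix of observation probabilities.
#' @export
obs_matrix <- function(pm, model) {
  pm <- unclass(pm)
  if (identical(model$obs, "renorm4")) {
    four <- pm[, c("S1", "systole", "S2", "diastole"), drop = FALSE]
    out <- four / pmax(rowSums(four), 1e-12)
  } else {
    out <- pm[, model$obs, drop = FALSE]
  }
  colnames(out) <- model$states
  out
}

# duration support and log-densities on the frame grid
duration_support <- function(model, frame_step = FRAME_STEP) {
  m <- model$duration_mean / frame_step
  s <- model$duration_sd / frame_step
  dmin <- pmax(1, round(m - 3 * s))
  dmax <- pmax(dmin, round(m + 3 * s))
  logdur <- lapply(seq_along(m), function(i) {
    dnorm(dmin[i]:dmax[i], m[i], s[i], log = TRUE)
  })
  list(dmin = as.integer(dmin), dmax = as.integer(dmax), logdur = logdur)
}

#' Duration-constrained Viterbi segmentation under one HSMM
#'
#' Finds the maximum-scoring state path where states follow the model's
#' cycle, each complete segment pays a Gaussian log duration density
#' (support truncated to mean +/- 3 sd, clipped to >= 1 frame), and the
#' first/last segments may be partial (observation cost only).  Observation
#' scores are the log posteriors of each decode state's observation column,
#' floored at 1e-12.
#'
#' @param pm A `pcg_posteriors` matrix.
#' @param model An `hsmm_model`.
#' @return A `pcg_segmentation`: `path` (factor of decode states),
#'   `confidence` (mean posterior along the path), `score`, `model_id`,
#'   `timing`.
#' @export
viterbi_duration <- function(pm, model) {
  obs <- obs_matrix(pm, model)
  sup <- duration_support(model)
  res <- viterbi_duration_cpp(log(pmax(obs, 1e-12)), sup$dmin, sup$dmax,
                              sup$logdur)
  path <- factor(model$states[res$path], levels = model$states)
  structure(
    list(path = path, score = res$score,
         confidence = segmentation_confidence(path, pm, model),
         model_id = model$model_id, timing = model$timing),
    class = "pcg_segmentation"
  )
}

#' Segmentation confidence along a decoded path
#'
#' The mean over frames of the posterior mass assigned to the decoded state,
#' each decode state reading its observation column (for `w1`, the
#' renormalised 4-state posteriors).  Lies in \[0, 1\]; high values mean the
#' model's interpretation matches the frame classifier frame-by-frame.
#'
#' @param path Factor/character decode-state sequence.
#' @param pm A `pcg_posteriors` matrix.
#' @param model The `hsmm_model` the path was decoded under.
#' @return Scalar confidence.
#' @export
segmentation_confidence <- function(path, pm, model) {
  obs <- obs_matrix(pm, model)
  mean(obs[cbind(seq_len(nrow(obs)), match(as.character(path), model$states))])
}

#' @export
print.pcg_segmentation <- function(x, ...) {
  cat(sprintf("<pcg_segmentation %s> %d frames, confidence %.3f\n",
              x$model_id, length(x$path), x$confidence))
  invisible(x)
}

#' Map decode states to the five canonical frame states
#'
#' `w4`'s sysA/sysB decode states are reported as systole.
#'
#' @param path Factor/character decode-state sequence.
#' @return Factor over the five canonical states.
#' @export
decode_to_states <- function(path) {
  x <- as.character(path)
  x[x %in% c("sysA", "sysB")] <- "systole"
  state_factor(x)
}

#' Decode under all four HSMMs and select the best interpretation
#'
#' Runs the four decoders, computes each segmentation confidence, and
#' selects the model with the largest confidence (ties to the lowest model
#' index).  The murmur confidence is the best murmur-model confidence, the
#' normal confidence is `w1`'s, and their difference is the murmur
#' likelihood; the chosen model's confidence serves as the signal-quality
#' estimate.  A murmur is predicted iff the chosen model is a murmur model,
#' typed by that model's timing.
#'
#' @param pm A `pcg_posteriors` matrix.
#' @param hr An `hr_estimate` (or bare bpm) used to scale state durations.
#' @param ... Passed to [build_model_bank()].
#' @return A `pcg_decision`: list with `decision` (one-row tibble: `chosen`,
#'   `C_w1`..`C_w4`, `C_M`, `C_N`, `C_MN`, `quality`, `murmur`, `timing`)
#'   and `segmentations` (the four `pcg_segmentation`s).
#' @export
decide <- function(pm, hr, ...) {
  bank <- build_model_bank(hr, ...)
  segs <- lapply(bank, function(m) viterbi_duration(pm, m))
  C <- vapply(segs, `[[`, 0, "confidence")
  k <- unname(which.max(C)) # ties -> lowest index
  C_M <- max(C[c("w2", "w3", "w4")])
  C_N <- unname(C["w1"])
  decision <- tibble::tibble(
    chosen = names(bank)[k],
    C_w1 = unname(C["w1"]), C_w2 = unname(C["w2"]),
    C_w3 = unname(C["w3"]), C_w4 = unname(C["w4"]),
    C_M = C_M, C_N = C_N, C_MN = C_M - C_N,
    quality = unname(C[k]),
    murmur = k > 1,
    timing = if (k > 1) bank[[k]]$timing else "none"
  )
  structure(list(decision = decision, segmentations = segs),
            class = "pcg_decision")
}

#' @export
print.pcg_decision <- function(x, ...) {
  d <- x$decision
  cat(sprintf(
    "<pcg_decision> chosen %s (quality %.3f): %s, C(M-N) = %+.3f\n",
    d$chosen, d$quality,
    if (d$murmur) paste0("murmur (", d$timing, ")") else "no murmur", d$C_MN))
  invisible(x)
}

#' End-to-end murmur detection for one recording
#'
#' Feature extraction, posterior prediction, heart-rate estimation and
#' parallel-HSMM decision in one call.
#'
#' @param rec A [pcg_recording()].
#' @param model A trained `murmur_rnn`.
#' @param ... Passed to [build_model_bank()].
#' @return One-row tibble: recording id and site, estimated bpm, the
#'   parallel-decision columns, plus a list-column `fit` holding the full
#'   `pcg_decision`.
#' @export
detect_murmur <- function(rec, model, ...) {
  pm <- predict_posteriors(model, extract_features(rec))
  hr <- estimate_heart_rate(not_diastole_series(pm))
  fit <- decide(pm, hr, ...)
  dplyr::bind_cols(
    tibble::tibble(recording_id = rec$recording_id, site = rec$site,
                   bpm = hr$bpm),
    fit$decision,
    tibble::tibble(fit = list(fit))
  )
}

#' Apply murmur detection across a cohort manifest
#'
#' @param manifest Tibble from [simulate_cohort()] (columns `patient_id`,
#'   `recording` list-column) or any tibble with a `recording` list-column
#'   of [pcg_recording()] objects.
#' @param model A trained `murmur_rnn`.
#' @param ... Passed to [build_model_bank()].
#' @return Tibble with one row per recording: manifest keys joined with the
#'   per-recording decision columns.
#' @export
segment_cohort <- function(manifest, model, ...) {
  stopifnot("recording" %in% names(manifest))
  res <- lapply(seq_len(nrow(manifest)), function(i) {
    det <- detect_murmur(manifest$recording[[i]], model, ...)
    det$fit <- NULL
    det$patient_id <- manifest$patient_id[i]
    det
  })
  dplyr::bind_rows(res)
}
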