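#' Simulated end-to-end murmur-detection experiment
#'
#' Generates a training and a held-out set of labelled synthetic recordings,
#' trains the recurrent frame classifier, and evaluates on the held-out set:
#' overall frame-segmentation accuracy of the classifier and the AUROC of
#' the parallel-HSMM murmur likelihood `C(M-N)` for per-recording murmur
#' detection.
#'
#' @param n_train,n_test Number of training / held-out recordings.
#' @param duration_s Recording length in seconds.
#' @param epochs Maximum training epochs (early stopping applies).
#' @param seed Integer seed controlling cohort generation and training.
#' @param verbose Print training progress.
#' @return List: `model` (trained `murmur_rnn`), `results` (held-out
#'   per-recording tibble with `C_MN`, `murmur`, `murmur_truth`, ...),
#'   `frame_accuracy`, `auroc`.
#' @export
run_detection_experiment <- function(n_train = 200, n_test = 100,
                                     duration_s = 8, epochs = 20,
                                     seed = 1L, verbose = FALSE) {
  make_set <- function(n, s) {
    man <- simulate_cohort(ceiling(n / 1.8), murmur_prevalence = 0.5,
                           unknown_rate = 0, duration_s = duration_s,
                           seed = s)
    if (nrow(man) < n) stop("cohort came up short; increase patient count")
    man[seq_len(n), ]
  }
  train_man <- make_set(n_train, seed)
  test_man <- make_set(n_test, seed + 1L)

  dat <- cohort_frame_data(train_man)
  model <- train_rnn(NULL, dat$features, dat$labels,
                     cfg = rnn_config(epochs = epochs, seed = seed + 2L),
                     verbose = verbose)

  test_dat <- cohort_frame_data(test_man)
  n_ok <- 0; n_frames <- 0
  for (i in seq_along(test_dat$features)) {
    pm <- predict_posteriors(model, test_dat$features[[i]])
    pred <- PCG_STATES[max.col(unclass(pm), ties.method = "first")]
    n_ok <- n_ok + sum(pred == as.character(test_dat$labels[[i]]))
    n_frames <- n_frames + length(pred)
  }
  results <- segment_cohort(test_man, model)
  results$murmur_truth <- test_man$murmur_label == "present"
  list(
    model = model,
    results = results,
    frame_accuracy = n_ok / n_frames,
    auroc = roc_curve(results$C_MN, results$murmur_truth)$auc
  )
}

#' Murmur-loudness sensitivity sweep
#'
#' Decodes fresh simulated recordings at increasing murmur intensity
#' (holosystolic, fixed seeds per level) and reports the mean murmur
#' likelihood per level — the pipeline's dose-response curve.
#'
#' @param model A trained `murmur_rnn`.
#' @param levels_db Murmur SNR levels in dB (relative to the S1 burst).
#' @param n_per_level Recordings per level.
#' @param duration_s Recording length.
#' @param seed Integer seed.
#' @return List: `by_level` (tibble `level_db`, `mean_C_MN`), `rank_cor`
#'   (Spearman correlation of level and mean likelihood).
#' @export
murmur_loudness_sweep <- function(model, levels_db = c(-24, -18, -12, -6, 0),
                                  n_per_level = 8, duration_s = 8,
                                  seed = 1L) {
  rows <- lapply(seq_along(levels_db), function(i) {
    cmn <- vapply(seq_len(n_per_level), function(j) {
      sim <- simulate_pcg(sim_config(
        heart_rate_bpm = c(60, 160), murmur = "holo",
        murmur_snr_db = levels_db[i], duration_s = duration_s,
        seed = seed + 1000L * i + j))
      detect_murmur(sim$recording, model)$C_MN
    }, 0)
    tibble::tibble(level_db = levels_db[i], mean_C_MN = mean(cmn))
  })
  by_level <- dplyr::bind_rows(rows)
  list(by_level = by_level,
       rank_cor = stats::cor(by_level$level_db, by_level$mean_C_MN,
                             method = "spearman"))
}

#' Heart-rate recovery study
#'
#' Simulates murmur-free recordings at fixed heart rates and measures the
#' absolute error of the posterior-autocorrelation estimate obtained
#' through the trained classifier.
#'
#' @param model A trained `murmur_rnn`.
#' @param rates_bpm True simulated rates.
#' @param n_seeds Recordings per rate.
#' @param duration_s Recording length (10 s gives the autocorrelation at
#'   least the 2 s lag the 30 bpm search bound needs).
#' @param seed Integer seed.
#' @return Tibble: `true_bpm`, `estimated_bpm`, `abs_error`.
#' @export
hr_recovery_study <- function(model, rates_bpm = c(60, 90, 120, 150, 180),
                              n_seeds = 10, duration_s = 10, seed = 1L) {
  rows <- list()
  for (bpm in rates_bpm) {
    for (j in seq_len(n_seeds)) {
      sim <- simulate_pcg(sim_config(heart_rate_bpm = bpm,
                                     duration_s = duration_s,
                                     seed = seed + 100L * bpm + j))
      hr <- heart_rate(sim$recording, model)
      rows[[length(rows) + 1]] <- tibble::tibble(
        true_bpm = bpm, estimated_bpm = hr$bpm,
        abs_error = abs(hr$bpm - bpm))
    }
  }
  dplyr::bind_rows(rows)
}
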