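test_that("a fixed seed reproduces waveform and intervals bit-for-bit", {
  a <- simulate_pcg(sim_config(murmur = "early", seed = 41, duration_s = 4))
  b <- simulate_pcg(sim_config(murmur = "early", seed = 41, duration_s = 4))
  expect_identical(a$recording$samples, b$recording$samples)
  expect_identical(a$intervals, b$intervals)
  c <- simulate_pcg(sim_config(murmur = "early", seed = 42, duration_s = 4))
  expect_false(identical(a$recording$samples, c$recording$samples))
})

test_that("ground-truth intervals follow the cardiac cycle", {
  sim <- simulate_pcg(sim_config(heart_rate_bpm = 120, murmur = "mid",
                                 duration_s = 8, seed = 43))
  iv <- sim$intervals
  expect_true(all(diff(iv$start) > 0))
  expect_true(all(iv$end[-nrow(iv)] - iv$start[-1] < 1e-9)) # contiguous
  # cyclic order: after S2 comes diastole, after diastole S1
  st <- as.character(iv$state)
  expect_true(all(st[which(st == "S2") + 1] == "diastole", na.rm = TRUE))
  after_dia <- st[which(st == "diastole") + 1]
  expect_true(all(after_dia == "S1", na.rm = TRUE))
  # murmur only inside systole (flanked by systole or S1/S2 boundaries)
  expect_true(all(st[which(st == "murmur") - 1] %in% c("systole", "S1")))
  # cycle count ~ duration * bpm / 60
  expect_lte(abs(sum(st == "S1") - 8 * 120 / 60), 1)
})

test_that("murmur intervals span the configured part of systole", {
  holo <- simulate_pcg(sim_config(heart_rate_bpm = 90, murmur = "holo",
                                  duration_s = 5, seed = 44))
  st <- as.character(holo$intervals$state)
  expect_false("systole" %in% st) # murmur replaces all of systole
  expect_true("murmur" %in% st)
  none <- simulate_pcg(sim_config(heart_rate_bpm = 90, murmur = "none",
                                  duration_s = 5, seed = 44))
  expect_false("murmur" %in% as.character(none$intervals$state))
  # early murmur takes half the systolic time
  early <- simulate_pcg(sim_config(heart_rate_bpm = 90, murmur = "early",
                                   duration_s = 5, seed = 45))
  iv <- early$intervals
  mur <- sum(iv$end[iv$state == "murmur"] - iv$start[iv$state == "murmur"])
  sys <- sum(iv$end[iv$state == "systole"] - iv$start[iv$state == "systole"])
  expect_equal(mur / (mur + sys), 0.5, tolerance = 0.05)
})

test_that("louder murmurs put more energy in the murmur band", {
  energy <- vapply(c(-18, -9, 0), function(snr) {
    sim <- simulate_pcg(sim_config(heart_rate_bpm = 80, murmur = "holo",
                                   murmur_snr_db = snr, noise_snr_db = 40,
                                   duration_s = 4, seed = 46))
    sf <- log_spectrogram(normalise_amplitude(sim$recording))
    lab <- suppressWarnings(
      intervals_to_frames(sim$intervals, nrow(sf$values)))
    band <- sf$freq >= 150 & sf$freq <= 350
    mean(sf$values[lab == "murmur", band])
  }, 0)
  expect_true(all(diff(energy) > 0))
})

test_that("cohorts are reproducible and write parseable artefacts", {
  d <- withr::local_tempdir()
  man <- simulate_cohort(4, murmur_prevalence = 0.5, duration_s = 3,
                         seed = 47, dir = d)
  man2 <- simulate_cohort(4, murmur_prevalence = 0.5, duration_s = 3,
                          seed = 47)
  expect_identical(man$recording_id, man2$recording_id)
  expect_identical(man$recording[[1]]$samples, man2$recording[[1]]$samples)
  expect_true(all(man$site %in% PCG_SITES))
  expect_true(all(table(man$patient_id) <= 4))
  # murmur-positive recordings carry 5-state ground truth on disk
  for (i in seq_len(nrow(man))) {
    rec <- read_recording(file.path(d, paste0(man$recording_id[i], ".wav")))
    expect_equal(rec$fs, 4000)
    iv <- read_segmentation(file.path(d, paste0(man$recording_id[i], ".tsv")))
    expect_gt(nrow(iv), 0)
    if (man$murmur_label[i] == "present") {
      expect_true("murmur" %in% as.character(iv$state))
    }
  }
  p <- read_patient(file.path(d, paste0(man$patient_id[1], ".txt")))
  expect_equal(p$patient_id, man$patient_id[1])
  expect_true(file.exists(file.path(d, "manifest.csv")))
})

test_that("murmur prevalence is approximately respected", {
  man <- simulate_cohort(60, murmur_prevalence = 0.3, duration_s = 2,
                         seed = 48)
  per_patient <- man[!duplicated(man$patient_id), ]
  frac <- mean(per_patient$murmur_label == "present")
  expect_gt(frac, 0.15); expect_lt(frac, 0.45) # binomial range
  # timing consistent across a patient's recordings
  for (pid in unique(man$patient_id)) {
    expect_length(unique(man$murmur_timing[man$patient_id == pid]), 1)
  }
})
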