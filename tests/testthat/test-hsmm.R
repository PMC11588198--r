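test_that("greedy segmentation is the per-frame argmax with tie rule", {
  pm <- diag(5)[c(1, 3, 5, 2, 4), ]
  colnames(pm) <- PCG_STATES
  expect_equal(as.character(greedy_segmentation(pm)),
               c("S1", "S2", "murmur", "systole", "diastole"))
  tie <- matrix(c(0.3, 0.3, 0.2, 0.1, 0.1), 1)
  colnames(tie) <- PCG_STATES
  expect_equal(as.character(greedy_segmentation(tie)), "S1")
  # unconstrained optimality: greedy mean posterior dominates random paths
  set.seed(21)
  r <- random_posteriors(40)
  g <- mean(r[cbind(1:40, as.integer(greedy_segmentation(r)))])
  for (i in 1:20) {
    p <- sample.int(5, 40, TRUE)
    expect_gte(g, mean(r[cbind(1:40, p)]))
  }
})

test_that("the model bank has the stated topologies and cycle lengths", {
  for (bpm in c(55, 90, 178)) {
    bank <- build_model_bank(bpm)
    expect_named(bank, c("w1", "w2", "w3", "w4"))
    expect_length(bank$w1$states, 4)
    expect_length(bank$w2$states, 4)
    expect_length(bank$w3$states, 5)
    expect_length(bank$w4$states, 6)
    for (m in bank) {
      expect_equal(sum(m$duration_mean), 60 / bpm, tolerance = 1e-9)
      expect_true(all(m$duration_mean > 0))
    }
    expect_equal(bank$w3$states[2], "murmur")  # S1 -> murmur -> systole
    expect_equal(bank$w4$states[2:4], c("sysA", "murmur", "sysB"))
  }
  expect_error(build_model_bank(400), "heart rate")
})

test_that("w1 discards murmur mass by renormalising the other four columns", {
  pm <- matrix(c(0.1, 0.6, 0.05, 0.05, 0.2), 3, 5, byrow = TRUE)
  colnames(pm) <- PCG_STATES
  bank <- build_model_bank(90)
  o1 <- obs_matrix(pm, bank$w1)
  expect_equal(unname(rowSums(o1)), rep(1, 3))
  expect_equal(unname(o1[1, "systole"]), 0.6 / 0.8)
  o2 <- obs_matrix(pm, bank$w2)
  expect_equal(unname(o2[, "systole"]), rep(0.2, 3)) # murmur column
  o4 <- obs_matrix(pm, bank$w4)
  expect_equal(o4[, "sysA"], o4[, "sysB"])
})

test_that("duration-explicit decoding matches exhaustive enumeration", {
  set.seed(14)
  for (rep in 1:25) {
    S <- sample(2:3, 1); T <- sample(6:12, 1)
    mean_f <- runif(S, 1.5, 4)
    sd_f <- pmax(0.5, mean_f * 0.4)
    dmin <- pmax(1, round(mean_f - 3 * sd_f))
    dmax <- pmax(dmin, round(mean_f + 3 * sd_f))
    logB <- matrix(log(runif(T * S, 0.01, 1)), T, S)
    logdur <- lapply(1:S, function(s) {
      dnorm(dmin[s]:dmax[s], mean_f[s], sd_f[s], log = TRUE)
    })
    got <- murmurscan:::viterbi_duration_cpp(logB, as.integer(dmin),
                                             as.integer(dmax), logdur)
    want <- brute_force_viterbi(logB, dmin, dmax, mean_f, sd_f)
    expect_equal(got$score, want$score, tolerance = 1e-9)
    expect_equal(as.integer(got$path), as.integer(want$path))
  }
})

test_that("a duration-feasible one-hot path is decoded exactly", {
  bank <- build_model_bank(60)
  m <- bank$w1
  # three full cycles of exactly the duration means
  d <- round(m$duration_mean / 0.02)
  truth <- rep(rep(m$states, 3), times = rep(d, 3))
  pm <- matrix(1e-6, length(truth), 5)
  colnames(pm) <- PCG_STATES
  pm[cbind(seq_along(truth), match(truth, PCG_STATES))] <- 1
  pm <- pm / rowSums(pm)
  seg <- viterbi_duration(pm, m)
  expect_equal(as.character(seg$path), truth)
  expect_gt(seg$confidence, 0.99)
})

test_that("decoded paths only use cyclic-successor transitions", {
  set.seed(15)
  for (rep in 1:8) {
    pm <- random_posteriors(80)
    bank <- build_model_bank(runif(1, 60, 170))
    for (m in bank) {
      seg <- viterbi_duration(pm, m)
      idx <- match(as.character(seg$path), m$states)
      steps <- idx[-1][idx[-1] != idx[-length(idx)]]
      from <- idx[-length(idx)][idx[-1] != idx[-length(idx)]]
      if (length(steps)) {
        expect_true(all(steps == (from %% length(m$states)) + 1))
      }
      # confidence equals its definition, recomputed here independently
      obs <- obs_matrix(pm, m)
      expect_equal(seg$confidence,
                   mean(obs[cbind(seq_len(80), idx)]), tolerance = 1e-12)
      expect_gte(seg$confidence, 0)
      expect_lte(seg$confidence, 1)
    }
  }
})

test_that("internal decoded segments respect the truncated duration support", {
  set.seed(16)
  pm <- random_posteriors(150)
  bank <- build_model_bank(100)
  for (m in bank) {
    seg <- viterbi_duration(pm, m)
    sup <- murmurscan:::duration_support(m)
    r <- rle(as.character(seg$path))
    if (length(r$lengths) > 2) {
      inner <- 2:(length(r$lengths) - 1)
      si <- match(r$values[inner], m$states)
      expect_true(all(r$lengths[inner] >= sup$dmin[si]))
      expect_true(all(r$lengths[inner] <= sup$dmax[si]))
    }
  }
})

test_that("confidence attains its bounds on degenerate posteriors", {
  bank <- build_model_bank(80)
  # uniform posteriors: any path under a 5-state model scores exactly 0.2
  pm <- matrix(0.2, 60, 5)
  colnames(pm) <- PCG_STATES
  seg3 <- viterbi_duration(pm, bank$w3)
  expect_equal(seg3$confidence, 0.2, tolerance = 1e-12)
  # all-mass-on-path posteriors give confidence 1
  d <- round(bank$w1$duration_mean / 0.02)
  truth <- rep(rep(bank$w1$states, 2), times = rep(d, 2))
  hot <- matrix(0, length(truth), 5)
  colnames(hot) <- PCG_STATES
  hot[cbind(seq_along(truth), match(truth, PCG_STATES))] <- 1
  expect_equal(segmentation_confidence(truth, hot, bank$w1), 1)
  # greedy path dominates any decoded path's confidence
  set.seed(17)
  r <- random_posteriors(70)
  g <- mean(r[cbind(1:70, as.integer(greedy_segmentation(r)))])
  for (m in bank) {
    raw <- viterbi_duration(r, m)
    p5 <- decode_to_states(raw$path)
    expect_lte(mean(r[cbind(1:70, as.integer(p5))]), g + 1e-12)
  }
})

test_that("parallel decision picks the generating model on clean signals", {
  cases <- list(
    list(murmur = "none", expect_m = FALSE),
    list(murmur = "holo", expect_m = TRUE),
    list(murmur = "early", expect_m = TRUE),
    list(murmur = "mid", expect_m = TRUE)
  )
  for (cs in cases) {
    sim <- simulate_pcg(sim_config(heart_rate_bpm = 95, murmur = cs$murmur,
                                   duration_s = 10, seed = 600))
    T <- n_frames_for(length(sim$recording$samples))
    pm <- oracle_posteriors(sim$intervals, T)
    hr <- estimate_heart_rate(not_diastole_series(pm))
    dec <- decide(pm, hr)
    expect_equal(dec$decision$murmur, cs$expect_m)
    if (cs$expect_m) {
      expect_gt(dec$decision$C_MN, 0)
      expect_true(dec$decision$chosen %in% c("w2", "w3", "w4"))
    } else {
      expect_lt(dec$decision$C_MN, 0)
      expect_equal(dec$decision$chosen, "w1")
    }
    # invariants of the decision record
    expect_equal(dec$decision$C_M,
                 max(dec$decision$C_w2, dec$decision$C_w3, dec$decision$C_w4))
    expect_equal(dec$decision$C_N, dec$decision$C_w1)
    expect_equal(dec$decision$C_MN, dec$decision$C_M - dec$decision$C_N)
  }
})

test_that("murmur timing is reported from the chosen model", {
  sim <- simulate_pcg(sim_config(heart_rate_bpm = 85, murmur = "early",
                                 duration_s = 10, seed = 601))
  T <- n_frames_for(length(sim$recording$samples))
  pm <- oracle_posteriors(sim$intervals, T)
  dec <- decide(pm, estimate_heart_rate(not_diastole_series(pm)))
  expect_equal(dec$decision$chosen, "w3")
  expect_equal(dec$decision$timing, "early-systolic")
})

test_that("adding murmur mass inside systole never lowers C(M-N)", {
  sim <- simulate_pcg(sim_config(heart_rate_bpm = 90, murmur = "none",
                                 duration_s = 10, seed = 602))
  T <- n_frames_for(length(sim$recording$samples))
  pm0 <- oracle_posteriors(sim$intervals, T, sharp = 0.8)
  hr <- estimate_heart_rate(not_diastole_series(pm0))
  lab <- suppressWarnings(intervals_to_frames(sim$intervals, T))
  sys <- which(lab == "systole")
  # murmur observation mass is injected additively: w1 ignores the murmur
  # column (its four columns and their renormalisation are untouched), so
  # C_N is constant while every murmur model can only gain
  cmn <- vapply(seq(0, 0.8, by = 0.1), function(delta) {
    pm <- pm0
    pm[sys, "murmur"] <- pm[sys, "murmur"] + delta
    decide(pm, hr)$decision$C_MN
  }, 0)
  expect_true(all(diff(cmn) >= -1e-9))
})
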