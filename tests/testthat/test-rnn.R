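test_that("model construction is seed-reproducible with the stated shape", {
  m1 <- build_rnn(rnn_config(seed = 9))
  m2 <- build_rnn(rnn_config(seed = 9))
  expect_identical(m1$params, m2$params)
  m3 <- build_rnn(rnn_config(seed = 10))
  expect_false(identical(m1$params, m3$params))
  # architecture constants: 3 BiGRU layers of 60, FC 60/40, 5 classes
  expect_equal(dim(m1$params$Wi1f), c(180, 41))
  expect_equal(dim(m1$params$Wi2b), c(180, 120))
  expect_equal(dim(m1$params$Wh3f), c(180, 60))
  expect_equal(dim(m1$params$Wfc1), c(60, 120))
  expect_equal(dim(m1$params$Wfc2), c(40, 60))
  expect_equal(dim(m1$params$Wout), c(5, 40))
  expect_equal(m1$cfg$dropout, 0.1)
})

test_that("posterior rows form a probability simplex, deterministically", {
  m <- build_rnn(rnn_config(seed = 5))
  set.seed(1)
  x <- matrix(rnorm(30 * 41), 30, 41)
  pm <- predict_posteriors(m, x)
  expect_equal(dim(pm), c(30, 5))
  expect_true(all(pm >= 0 & pm <= 1))
  expect_equal(unname(rowSums(pm)), rep(1, 30), tolerance = 1e-6)
  expect_identical(unclass(pm), unclass(predict_posteriors(m, x)))
  expect_error(predict_posteriors(m, matrix(0, 10, 17)), "41")
})

test_that("analytic gradients match finite differences on a tiny model", {
  cfg <- rnn_config(hidden = 3, fc_sizes = c(4, 3), n_features = 5, seed = 7)
  m <- build_rnn(cfg)
  set.seed(42)
  x <- lapply(1:2, function(i) matrix(rnorm(6 * 5), 6, 5))
  y <- matrix(sample(1:5, 12, TRUE), 6, 2)
  w <- runif(5, 0.5, 2)
  g <- murmurscan:::gru_run(m$params, x, y, w, 0, FALSE, TRUE, FALSE)$grads
  eps <- 1e-6
  for (nm in c("Wi1f", "Wh2b", "bi3f", "Wfc1", "Wout", "bout")) {
    i <- sample(length(m$params[[nm]]), 1)
    bump <- function(h) {
      p <- m$params; p[[nm]][i] <- p[[nm]][i] + h
      murmurscan:::gru_run(p, x, y, w, 0, FALSE, FALSE, FALSE)$loss
    }
    num <- (bump(eps) - bump(-eps)) / (2 * eps)
    expect_equal(g[[nm]][i], num, tolerance = 1e-3)
  }
})

test_that("class weights are inverse-frequency, mean 1", {
  mk <- function(counts) {
    structure(state_factor(rep(PCG_STATES, counts)), frame_step = 0.02,
              class = c("frame_labels", "factor"))
  }
  expect_equal(unname(class_weights(mk(c(10, 10, 10, 10, 10)))), rep(1, 5))
  # hand computation: 1/c rescaled to mean 1 -> (5, 10, 10, 20, 20) / 13
  w <- class_weights(mk(c(40, 20, 20, 10, 10)))
  expect_equal(unname(w), c(5, 10, 10, 20, 20) / 13, tolerance = 1e-12)
  expect_equal(mean(w), 1)
  # scale invariance
  expect_equal(class_weights(mk(2 * c(40, 20, 20, 10, 10))), w)
  expect_error(class_weights(mk(c(10, 10, 10, 10, 0))), "murmur")
})

test_that("training overfits one recording and is seed-deterministic", {
  sim <- simulate_pcg(sim_config(heart_rate_bpm = 90, murmur = "early",
                                 duration_s = 6, seed = 8))
  sf <- extract_features(sim$recording)
  lab <- intervals_to_frames(sim$intervals, nrow(sf$values))
  cfg <- rnn_config(epochs = 60, patience = 60, seed = 5)
  m <- train_rnn(NULL, list(sf), list(lab), cfg = cfg)
  pm <- predict_posteriors(m, sf)
  acc <- mean(PCG_STATES[max.col(pm, ties.method = "first")] ==
                as.character(lab))
  expect_gte(acc, 0.99)
  expect_true(all(tidy(m)$train_loss >= 0))

  cfg2 <- rnn_config(epochs = 3, patience = 3, seed = 31)
  ma <- train_rnn(NULL, list(sf), list(lab), cfg = cfg2)
  mb <- train_rnn(NULL, list(sf), list(lab), cfg = cfg2)
  expect_identical(ma$params, mb$params)
  expect_equal(tidy(ma)$train_loss, tidy(mb)$train_loss)

  expect_error(train_rnn(NULL, list(sf), list(lab[-1])), "mismatch")
})

test_that("trained model separates murmur from diastole posteriors", {
  model <- get_demo_model()
  sim <- simulate_pcg(sim_config(heart_rate_bpm = 100, murmur = "holo",
                                 murmur_snr_db = 0, duration_s = 6,
                                 seed = 77))
  sf <- extract_features(sim$recording)
  lab <- intervals_to_frames(sim$intervals, nrow(sf$values))
  pm <- predict_posteriors(model, sf)
  mur <- mean(pm[lab == "murmur", "murmur"])
  dia <- mean(pm[lab == "diastole", "murmur"])
  expect_gt(mur, dia)
  # held-out frame accuracy beats the prior baseline by a wide margin
  acc <- mean(PCG_STATES[max.col(pm, ties.method = "first")] ==
                as.character(lab))
  expect_gt(acc, max(prop.table(table(lab))))
})
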