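test_that("confusion construction counts predicted x true", {
  cm <- murmur_confusion(c("present", "absent", "absent", "unknown"),
                         c("present", "absent", "present", "unknown"))
  expect_equal(sum(cm), 4)
  expect_equal(cm["present", "present"], 1)
  expect_equal(cm["absent", "present"], 1)
  expect_error(murmur_confusion("maybe", "present"), "present/unknown/absent")
})

test_that("weighted accuracy follows the 5:3:1 true-class weighting", {
  cm <- reference_confusion()
  # identity on the reference matrix checked in the acceptance suite; here
  # the formula's edge cases
  expect_equal(weighted_accuracy(diag(c(10, 5, 2))), 1)
  # all-absent predictor on the reference counts: 695 / 1794
  all_absent <- rbind(0, 0, colSums(cm))
  expect_equal(weighted_accuracy(all_absent), 695 / 1794, tolerance = 1e-12)
  # with unit weights it reduces to micro accuracy
  expect_equal(weighted_accuracy(cm, weights = c(1, 1, 1)),
               sum(diag(cm)) / sum(cm), tolerance = 1e-12)
  expect_error(weighted_accuracy(matrix(0, 3, 3)), "empty")
})

test_that("per-class statistics handle diagonal and degenerate matrices", {
  d <- diag(c(4, 3, 2))
  s <- per_class_stats(d)
  expect_equal(s$sensitivity, rep(1, 3))
  expect_equal(s$ppv, rep(1, 3))
  expect_equal(s$f1, rep(1, 3))
  # a never-predicted class has undefined PPV, reported NA not 0
  cm <- rbind(c(5, 2, 0), c(0, 0, 0), c(1, 3, 7))
  expect_warning(s2 <- per_class_stats(cm), "undefined")
  expect_true(is.na(s2$ppv[2]))
  expect_equal(s2$sensitivity[2], 0)
})

test_that("Youden's index is sensitivity + specificity - 1", {
  expect_equal(youden(0.423, 0.889), 0.312)
  expect_equal(youden(1, 1), 1)
  sens <- runif(10)
  expect_equal(youden(sens, 1 - sens), rep(0, 10)) # ROC diagonal
  expect_error(youden(1.2, 0.5))
})

test_that("AUC equals the rank-sum oracle and pROC on small inputs", {
  # all-pairs oracle: P(score_pos > score_neg) + 0.5 P(tie)
  rank_auc <- function(s, y) {
    pos <- s[y == 1]; neg <- s[y == 0]
    mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
  }
  s <- c(0.3, 0.1, 0.2, 0.0)
  y <- c(1, 1, 0, 0)
  r <- roc_curve(s, y)
  expect_equal(r$auc, 0.75)
  expect_equal(r$auc, rank_auc(s, y))
  # perfectly separated scores
  expect_equal(roc_curve(c(3, 4, 1, 2), c(1, 1, 0, 0))$auc, 1)
  # label swap symmetry
  expect_equal(roc_curve(s, 1 - y)$auc, 1 - r$auc)
  set.seed(19)
  for (i in 1:10) {
    s <- round(runif(30), 2) # ties likely
    y <- rbinom(30, 1, 0.5)
    if (length(unique(y)) < 2) next
    expect_equal(roc_curve(s, y)$auc, rank_auc(s, y), tolerance = 1e-12)
    expect_equal(roc_curve(s, y)$auc,
                 as.numeric(pROC::auc(pROC::roc(y, s, direction = "<",
                                                levels = c(0, 1),
                                                quiet = TRUE))),
                 tolerance = 1e-12)
  }
  expect_error(roc_curve(runif(5), rep(1, 5)), "both classes")
  expect_error(roc_curve(runif(3), c("present", "unknown", "absent")),
               "unknown")
})

test_that("bootstrap CI brackets the point AUC and is seed-stable", {
  set.seed(20)
  s <- c(rnorm(40, 1), rnorm(40))
  y <- rep(c(1, 0), each = 40)
  r1 <- roc_curve(s, y, n_boot = 200, seed = 5)
  r2 <- roc_curve(s, y, n_boot = 200, seed = 5)
  expect_equal(r1$auc_ci, r2$auc_ci)
  expect_lte(r1$auc_ci[1], r1$auc)
  expect_gte(r1$auc_ci[2], r1$auc)
})

test_that("reliability bins trace calibration", {
  expect_equal(reliability_bins(runif(50), rep(1, 50), 5)$frequency,
               rep(1, length(unique(reliability_bins(runif(50), rep(1, 50), 5)$bin))))
  set.seed(22)
  s <- runif(4000)
  y <- rbinom(4000, 1, s) # perfectly calibrated by construction
  b <- reliability_bins(s, y, 8)
  expect_true(all(b$frequency >= 0 & b$frequency <= 1))
  expect_true(all(diff(b$frequency) > -0.1)) # monotone up to binomial noise
  expect_equal(nrow(b), 8)
  # empty bins are dropped
  b2 <- reliability_bins(c(0, 0.01, 1), c(0, 0, 1), 10)
  expect_lt(nrow(b2), 10)
})
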