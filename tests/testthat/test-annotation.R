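test_that("rasterisation assigns each frame the state at its centre", {
  iv <- tibble::tibble(start = c(0, 0.10), end = c(0.10, 0.30),
                       state = factor(c("S1", "systole"), levels = PCG_STATES))
  lab <- intervals_to_frames(iv, 5)
  # independent hand rasterisation: centres (t-1)*20ms + 25ms
  centres <- (0:4) * 0.020 + 0.025
  want <- ifelse(centres < 0.10, "S1", "systole")
  expect_equal(as.character(lab), want)

  # single interval covering everything -> all frames that state
  one <- tibble::tibble(start = 0, end = 1,
                        state = factor("diastole", levels = PCG_STATES))
  expect_equal(unique(as.character(intervals_to_frames(one, 40))), "diastole")

  # zero-length interval contributes no frames
  iv0 <- tibble::tibble(start = c(0, 0.10, 0.10), end = c(0.10, 0.10, 0.30),
                        state = factor(c("S1", "systole", "diastole"),
                                       levels = PCG_STATES))
  lab0 <- intervals_to_frames(iv0, 5)
  expect_false("systole" %in% as.character(lab0))

  # frame centres outside all intervals take the nearest state, with warning
  short <- tibble::tibble(start = 0, end = 0.05,
                          state = factor("S1", levels = PCG_STATES))
  expect_warning(lab2 <- intervals_to_frames(short, 3), "nearest")
  expect_equal(as.character(lab2), rep("S1", 3))
})

test_that("murmur expansion follows the timing label per systole run", {
  mk <- function(x) structure(factor(x, levels = PCG_STATES),
                              frame_step = 0.02,
                              class = c("frame_labels", "factor"))
  base <- mk(c("S1", "S1", rep("systole", 4), "S2", rep("diastole", 3)))

  early <- expand_murmur(base, "early-systolic")
  expect_equal(as.character(early)[3:6], c("murmur", "murmur", "systole", "systole"))

  holo <- expand_murmur(base, "holosystolic")
  expect_equal(as.character(holo)[3:6], rep("murmur", 4))

  mid <- expand_murmur(base, "mid-systolic")
  expect_equal(as.character(mid)[3:6], c("systole", "murmur", "murmur", "systole"))

  expect_identical(expand_murmur(base, "none"), base)

  # odd-length run: 50% rounds up (ceil), mid offset floor(L/4)
  odd <- mk(c("S1", rep("systole", 5), "S2"))
  expect_equal(sum(expand_murmur(odd, "early-systolic") == "murmur"), 3)
  mid5 <- expand_murmur(odd, "mid-systolic")
  expect_equal(which(as.character(mid5) == "murmur"), c(3, 4, 5))
})

test_that("expansion never alters non-systole frames and is idempotent", {
  set.seed(4)
  for (timing in c("early-systolic", "mid-systolic", "holosystolic")) {
    x <- sample(c("S1", "systole", "S2", "diastole"), 60, TRUE)
    lab <- structure(factor(x, levels = PCG_STATES), frame_step = 0.02,
                     class = c("frame_labels", "factor"))
    out <- expand_murmur(lab, timing)
    keep <- x != "systole"
    expect_equal(as.character(out)[keep], x[keep])
    # per-run murmur count: ceil(L/2) for early/mid, L for holo
    r <- rle(x == "systole")
    runs <- r$lengths[r$values]
    want <- if (timing == "holosystolic") sum(runs) else sum(ceiling(runs / 2))
    expect_equal(sum(out == "murmur"), want)
    expect_identical(expand_murmur(out, timing), out)
  }
})

test_that("frames_to_intervals merges runs onto the frame-step grid", {
  states <- c("S1", "S1", "systole", "systole", "S2", "diastole")
  iv <- frames_to_intervals(states)
  expect_equal(nrow(iv), 4)
  expect_equal(iv$start, c(0, 0.04, 0.08, 0.10))
  expect_equal(iv$end, c(0.04, 0.08, 0.10, 0.12))
  expect_equal(as.character(iv$state), c("S1", "systole", "S2", "diastole"))
})
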