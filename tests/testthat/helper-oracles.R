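# Independent oracles and shared fixtures, built in code.

# Exhaustive enumeration of all duration-valid segmentations of a cyclic
# HSMM: entry state x all boundary compositions of T frames.  Complete
# segments pay a Gaussian log duration density; the first/last segment may
# be partial (observation cost only, length <= dmax); a single segment
# spanning the whole recording may be up to 2*dmax.  Independent of the
# dynamic-programming decoder.
brute_force_viterbi <- function(logB, dmin, dmax, mean_f, sd_f) {
  T <- nrow(logB); S <- ncol(logB)
  cum <- apply(logB, 2, cumsum)
  seg <- function(a, b, s) if (a == 1) cum[b, s] else cum[b, s] - cum[a - 1, s]
  best <- list(score = -Inf, path = NULL)
  for (entry in 1:S) {
    for (mask in 0:(2^(T - 1) - 1)) {
      bps <- which(bitwAnd(mask, 2^(0:(T - 2))) > 0)
      starts <- c(1, bps + 1); ends <- c(bps, T)
      k <- length(starts)
      states <- ((entry - 1 + seq_len(k) - 1) %% S) + 1
      sc <- 0; ok <- TRUE
      for (j in seq_len(k)) {
        d <- ends[j] - starts[j] + 1
        s <- states[j]
        if (j == 1 && j == k) {
          if (d > 2 * dmax[s]) { ok <- FALSE; break }
        } else if (j == 1 || j == k) {
          if (d > dmax[s]) { ok <- FALSE; break }
        } else {
          if (d < dmin[s] || d > dmax[s]) { ok <- FALSE; break }
          sc <- sc + dnorm(d, mean_f[s], sd_f[s], log = TRUE)
        }
        sc <- sc + seg(starts[j], ends[j], s)
      }
      if (ok && sc > best$score) {
        best <- list(score = sc, path = rep(states, ends - starts + 1))
      }
    }
  }
  best
}

# Sharp synthetic posteriors derived from ground-truth intervals: the true
# state gets mass `sharp`, the rest is spread uniformly.  Lets HSMM-level
# behaviour be tested without a trained network.
oracle_posteriors <- function(intervals, n_frames, sharp = 0.9) {
  lab <- suppressWarnings(intervals_to_frames(intervals, n_frames))
  pm <- matrix((1 - sharp) / 4, n_frames, 5)
  colnames(pm) <- PCG_STATES
  pm[cbind(seq_len(n_frames), as.integer(lab))] <- sharp
  structure(pm, class = c("pcg_posteriors", class(pm)))
}

# random row-stochastic posterior matrix
random_posteriors <- function(n_frames) {
  pm <- matrix(runif(n_frames * 5), n_frames, 5)
  pm <- pm / rowSums(pm)
  colnames(pm) <- PCG_STATES
  structure(pm, class = c("pcg_posteriors", class(pm)))
}

# small trained classifier shared across test files (trained at most once
# per test run)
.model_cache <- new.env(parent = emptyenv())
get_demo_model <- function() {
  if (is.null(.model_cache$model)) {
    man <- simulate_cohort(10, murmur_prevalence = 0.5, unknown_rate = 0,
                           duration_s = 6, seed = 424)
    dat <- cohort_frame_data(man)
    .model_cache$manifest <- man
    .model_cache$model <- train_rnn(
      NULL, dat$features, dat$labels,
      cfg = rnn_config(epochs = 12, patience = 12, seed = 424))
  }
  .model_cache$model
}

# reference cross-validated murmur confusion matrix (predicted x true)
reference_confusion <- function() {
  path <- system.file("extdata", "murmur_confusion_reference.csv",
                      package = "murmurscan")
  m <- as.matrix(read.csv(path, row.names = 1))
  dimnames(m) <- list(predicted = rownames(m), truth = colnames(m))
  m
}
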