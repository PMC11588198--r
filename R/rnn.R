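#' Configuration for the recurrent frame classifier
#'
#' The architecture is a three-layer bidirectional GRU with hidden size 60;
#' the concatenated forward/backward outputs pass through two fully
#' connected layers (sizes 60 and 40) with Tanh activations and a softmax
#' head over the five frame states, with dropout 0.1 between the GRU stack
#' and the FC head.  Optimiser defaults (Adam, learning rate 1e-3, batch
#' size 16 recordings, up to 30 epochs with early stopping) are tunable.
#'
#' @param rnn_layers Number of stacked bidirectional GRU layers.
#' @param hidden GRU hidden size per direction.
#' @param fc_sizes Sizes of the two fully connected layers.
#' @param dropout Dropout probability between GRU stack and FC head.
#' @param classes Number of output states.
#' @param n_features Input feature bins per frame (41 spectrogram bins).
#' @param learning_rate,epochs,batch_size,patience,val_frac Optimiser
#'   settings; `patience` is the early-stopping patience in epochs and
#'   `val_frac` the fraction of recordings held out for validation.
#' @param seed Integer seed controlling weight initialisation, batch order
#'   and dropout.
#' @return A list of class `rnn_config`.
#' @export
rnn_config <- function(rnn_layers = 3, hidden = 60, fc_sizes = c(60, 40),
                       dropout = 0.1, classes = 5, n_features = 41,
                       learning_rate = 1e-3, epochs = 30, batch_size = 16,
                       patience = 5, val_frac = 0.15, seed = 1L) {
  stopifnot(rnn_layers == 3, hidden > 0, length(fc_sizes) == 2,
            all(fc_sizes > 0), dropout >= 0, dropout < 1, classes > 0,
            n_features > 0, learning_rate > 0, epochs >= 1, batch_size >= 1)
  structure(as.list(environment()), class = "rnn_config")
}

init_mat <- function(nr, nc, k) matrix(runif(nr * nc, -k, k), nr, nc)

#' Build an untrained recurrent frame classifier
#'
#' Initialises all weights uniformly in `[-1/sqrt(hidden), 1/sqrt(hidden)]`
#' (FC layers use their own fan-in) using the current RNG state, after
#' seeding from `cfg$seed`.
#'
#' @param cfg An [rnn_config()].
#' @return An object of class `murmur_rnn` with elements `cfg`, `params`,
#'   `class_weights`, `log` and `trained`.
#' @export
build_rnn <- function(cfg = rnn_config()) {
  stopifnot(inherits(cfg, "rnn_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  H <- cfg$hidden
  k <- 1 / sqrt(H)
  params <- list()
  for (l in 1:cfg$rnn_layers) {
    n_in <- if (l == 1) cfg$n_features else 2 * H
    for (d in c("f", "b")) {
      params[[paste0("Wi", l, d)]] <- init_mat(3 * H, n_in, k)
      params[[paste0("Wh", l, d)]] <- init_mat(3 * H, H, k)
      params[[paste0("bi", l, d)]] <- runif(3 * H, -k, k)
      params[[paste0("bh", l, d)]] <- runif(3 * H, -k, k)
    }
  }
  f1 <- cfg$fc_sizes[1]; f2 <- cfg$fc_sizes[2]
  params$Wfc1 <- init_mat(f1, 2 * H, 1 / sqrt(2 * H))
  params$bfc1 <- runif(f1, -1 / sqrt(2 * H), 1 / sqrt(2 * H))
  params$Wfc2 <- init_mat(f2, f1, 1 / sqrt(f1))
  params$bfc2 <- runif(f2, -1 / sqrt(f1), 1 / sqrt(f1))
  params$Wout <- init_mat(cfg$classes, f2, 1 / sqrt(f2))
  params$bout <- runif(cfg$classes, -1 / sqrt(f2), 1 / sqrt(f2))
  structure(
    list(cfg = cfg, params = params, class_weights = rep(1, cfg$classes),
         log = NULL, trained = FALSE),
    class = "murmur_rnn"
  )
}

#' @export
print.murmur_rnn <- function(x, ...) {
  n_par <- sum(vapply(x$params, length, 1L))
  cat(sprintf(paste0("<murmur_rnn> %d-layer BiGRU(h=%d) + FC(%s) -> %d states; ",
                     "%d parameters; %s\n"),
              x$cfg$rnn_layers, x$cfg$hidden,
              paste(x$cfg$fc_sizes, collapse = ","), x$cfg$classes,
              n_par, if (x$trained) "trained" else "untrained"))
  invisible(x)
}

#' Inverse-frequency class weights
#'
#' Rare frame states (murmur, S1, S2) would otherwise be dominated by the
#' prevalent diastole frames in the cross-entropy loss.  Weights are
#' proportional to `1 / count` and rescaled so the mean weight is 1.
#'
#' @param labels A `frame_labels` object or a list of them.
#' @return Named numeric vector of 5 weights in state order.
#' @export
class_weights <- function(labels) {
  if (!is.list(labels)) labels <- list(labels)
  counts <- Reduce(`+`, lapply(labels, function(l) table(state_factor(as.character(l)))))
  counts <- as.numeric(counts)
  if (any(counts == 0)) {
    stop("class absent from labels: ",
         paste(PCG_STATES[counts == 0], collapse = ", "))
  }
  w <- (1 / counts) / mean(1 / counts)
  setNames(w, PCG_STATES)
}

adam_step <- function(par, grad, state, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  for (nm in names(par)) {
    g <- grad[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    par[[nm]] <- par[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(par = par, state = state)
}

labels_to_int <- function(labels) {
  as.integer(state_factor(as.character(labels)))
}

# group recording indices into batches of equal sequence length
make_batches <- function(lens, batch_size, shuffle = TRUE) {
  ord <- seq_along(lens)
  if (shuffle) ord <- sample(ord)
  batches <- list()
  for (L in unique(lens[ord])) {
    grp <- ord[lens[ord] == L]
    splits <- split(grp, ceiling(seq_along(grp) / batch_size))
    batches <- c(batches, unname(splits))
  }
  if (shuffle) batches <- sample(batches)
  batches
}

eval_batches <- function(params, feats, labs, w, batch_size) {
  lens <- vapply(feats, nrow, 1L)
  loss_sum <- 0; wt_sum <- 0; n_ok <- 0; n_tot <- 0
  for (idx in make_batches(lens, batch_size, shuffle = FALSE)) {
    y <- vapply(labs[idx], identity, integer(lens[idx[1]]))
    if (is.null(dim(y))) y <- matrix(y, ncol = length(idx))
    res <- gru_run(params, feats[idx], y, w, 0, FALSE, FALSE, TRUE)
    nf <- lens[idx[1]] * length(idx)
    loss_sum <- loss_sum + res$loss * nf
    wt_sum <- wt_sum + nf
    for (j in seq_along(idx)) {
      pred <- max.col(res$probs[[j]], ties.method = "first")
      n_ok <- n_ok + sum(pred == labs[[idx[j]]])
      n_tot <- n_tot + length(pred)
    }
  }
  list(loss = loss_sum / wt_sum, acc = n_ok / n_tot)
}

#' Train the recurrent frame classifier
#'
#' Minimises the class-weighted cross-entropy with Adam.  Recordings are
#' grouped into equal-length batches (no padding, so class weights are
#' undistorted), a fraction of recordings is held out for validation, and
#' the parameters with the lowest validation loss are returned.  Fully
#' seeded: the same `cfg$seed` reproduces initialisation, batch order,
#' dropout and hence the final model bit-for-bit.
#'
#' @param model A `murmur_rnn` from [build_rnn()]; built internally when
#'   `NULL`.
#' @param features List of z-scored `pcg_spectrogram` objects (or bare
#'   T x 41 matrices).
#' @param labels List of `frame_labels` aligned with `features`.
#' @param cfg Optional [rnn_config()] overriding `model$cfg`.
#' @param verbose Print per-epoch progress.
#' @return The trained `murmur_rnn`; `$log` holds the per-epoch training
#'   curve (tibble: epoch, train_loss, val_loss, val_acc).
#' @export
train_rnn <- function(model = NULL, features, labels, cfg = NULL, verbose = FALSE) {
  stopifnot(length(features) >= 1, length(features) == length(labels))
  feats <- lapply(features, function(f) {
    if (inherits(f, "pcg_spectrogram")) f$values else f
  })
  cfg <- cfg %||% (if (!is.null(model)) model$cfg else rnn_config())
  if (is.null(model)) model <- build_rnn(cfg)
  bad <- which(vapply(feats, nrow, 1L) != lengths(labels))
  if (length(bad)) stop("features/labels length mismatch at recording ", bad[1])
  if (any(vapply(feats, ncol, 1L) != cfg$n_features)) {
    stop("expected ", cfg$n_features, " feature bins per frame")
  }

  labs <- lapply(labels, labels_to_int)
  w <- unname(class_weights(labels))
  set.seed(cfg$seed)

  n <- length(feats)
  n_val <- if (n >= 7) max(1L, round(cfg$val_frac * n)) else 0L
  val_idx <- if (n_val > 0) sample(n, n_val) else integer()
  tr_idx <- setdiff(seq_len(n), val_idx)

  params <- model$params
  zero <- lapply(params, function(p) p * 0)
  st <- list(m = zero, v = zero, t = 0)
  lens <- vapply(feats, nrow, 1L)

  best <- list(loss = Inf, params = params, epoch = 0L)
  log <- vector("list", cfg$epochs)
  for (ep in seq_len(cfg$epochs)) {
    tr_loss <- 0; tr_frames <- 0
    for (idx in make_batches(lens[tr_idx], cfg$batch_size)) {
      idx <- tr_idx[idx]
      y <- vapply(labs[idx], identity, integer(lens[idx[1]]))
      if (is.null(dim(y))) y <- matrix(y, ncol = length(idx))
      res <- gru_run(params, feats[idx], y, w, cfg$dropout, TRUE, TRUE, FALSE)
      upd <- adam_step(params, res$grads, st, cfg$learning_rate)
      params <- upd$par; st <- upd$state
      nf <- lens[idx[1]] * length(idx)
      tr_loss <- tr_loss + res$loss * nf; tr_frames <- tr_frames + nf
    }
    val <- if (n_val > 0) {
      eval_batches(params, feats[val_idx], labs[val_idx], w, cfg$batch_size)
    } else {
      eval_batches(params, feats[tr_idx], labs[tr_idx], w, cfg$batch_size)
    }
    log[[ep]] <- tibble::tibble(epoch = ep, train_loss = tr_loss / tr_frames,
                                val_loss = val$loss, val_acc = val$acc)
    if (verbose) {
      message(sprintf("epoch %d: train %.4f val %.4f acc %.3f",
                      ep, tr_loss / tr_frames, val$loss, val$acc))
    }
    if (val$loss < best$loss - 1e-6) {
      best <- list(loss = val$loss, params = params, epoch = ep)
    } else if (ep - best$epoch >= cfg$patience) break
  }

  model$params <- best$params
  model$class_weights <- setNames(w, PCG_STATES)
  model$log <- dplyr::bind_rows(log[!vapply(log, is.null, TRUE)])
  model$trained <- TRUE
  model
}

#' Per-frame state posteriors from the trained classifier
#'
#' Runs the network in inference mode (dropout disabled); output rows are
#' probability vectors over (S1, systole, S2, diastole, murmur).
#'
#' @param model A `murmur_rnn`.
#' @param sf A z-scored `pcg_spectrogram` or a T x 41 matrix.
#' @return A `pcg_posteriors` matrix (T x 5, row-stochastic).
#' @export
predict_posteriors <- function(model, sf) {
  stopifnot(inherits(model, "murmur_rnn"))
  x <- if (inherits(sf, "pcg_spectrogram")) sf$values else sf
  if (ncol(x) != model$cfg$n_features) {
    stop("expected ", model$cfg$n_features, " feature bins, got ", ncol(x))
  }
  res <- gru_run(model$params, list(x), NULL, rep(1, model$cfg$classes),
                 0, FALSE, FALSE, TRUE)
  pm <- res$probs[[1]]
  colnames(pm) <- PCG_STATES
  structure(pm, class = c("pcg_posteriors", class(pm)))
}
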