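#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the training curve of a frame classifier
#'
#' @param x A `murmur_rnn`.
#' @param ... Unused.
#' @return Tibble with one row per epoch: `epoch`, `train_loss`,
#'   `val_loss`, `val_acc`.
#' @export
tidy.murmur_rnn <- function(x, ...) {
  x$log %||% tibble::tibble(epoch = integer(), train_loss = numeric(),
                            val_loss = numeric(), val_acc = numeric())
}

#' One-row summary of a frame classifier
#'
#' @param x A `murmur_rnn`.
#' @param ... Unused.
#' @return Tibble: parameter count, epochs run, best validation loss and
#'   accuracy.
#' @export
glance.murmur_rnn <- function(x, ...) {
  log <- tidy(x)
  tibble::tibble(
    n_parameters = sum(vapply(x$params, length, 1L)),
    trained = x$trained,
    epochs_run = nrow(log),
    best_val_loss = if (nrow(log)) min(log$val_loss) else NA_real_,
    best_val_acc = if (nrow(log)) max(log$val_acc) else NA_real_
  )
}

#' Tidy a parallel-HSMM decision
#'
#' @param x A `pcg_decision` from [decide()].
#' @param ... Unused.
#' @return Tibble with one row per candidate model: `model`, `confidence`,
#'   `chosen`, `timing`.
#' @export
tidy.pcg_decision <- function(x, ...) {
  tibble::tibble(
    model = vapply(x$segmentations, `[[`, "", "model_id"),
    confidence = vapply(x$segmentations, `[[`, 0, "confidence"),
    timing = vapply(x$segmentations, `[[`, "", "timing"),
    chosen = vapply(x$segmentations, `[[`, "", "model_id") == x$decision$chosen
  )
}

#' One-row summary of a parallel-HSMM decision
#'
#' @param x A `pcg_decision`.
#' @param ... Unused.
#' @return The decision tibble (`chosen`, confidences, `C_MN`, `quality`,
#'   `murmur`, `timing`).
#' @export
glance.pcg_decision <- function(x, ...) x$decision

#' Tidy a decoded segmentation into intervals
#'
#' @param x A `pcg_segmentation` from [viterbi_duration()].
#' @param ... Unused.
#' @return Tibble of half-open intervals (`start`, `end`, `state`) on the
#'   canonical five-state alphabet.
#' @export
tidy.pcg_segmentation <- function(x, ...) {
  frames_to_intervals(decode_to_states(x$path))
}

#' Feature importance of the outcome classifier
#'
#' @param x An `outcome_model`.
#' @param ... Unused.
#' @return Tibble of per-feature gain/cover/frequency importance.
#' @export
tidy.outcome_model <- function(x, ...) {
  imp <- xgboost::xgb.importance(model = x$booster)
  tibble::as_tibble(imp)
}

#' One-row summary of the outcome classifier
#'
#' @param x An `outcome_model`.
#' @param ... Unused.
#' @return Tibble: depth, class weight, rounds used, threshold.
#' @export
glance.outcome_model <- function(x, ...) {
  tibble::tibble(
    max_depth = x$params$max_depth,
    abnormal_weight = x$params$abnormal_weight,
    nrounds = x$params$nrounds,
    best_iteration = as.numeric(xgboost::xgb.attributes(x$booster)$best_iteration
                                %||% x$params$nrounds),
    threshold = x$threshold
  )
}
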