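MURMUR_CLASSES <- c("present", "unknown", "absent")

#' Build the 3x3 murmur confusion matrix
#'
#' Rows are predicted class, columns true class, both ordered
#' (present, unknown, absent).
#'
#' @param predicted,truth Vectors of patient labels in
#'   `{present, unknown, absent}`.
#' @return Integer 3x3 matrix of class `murmur_confusion`.
#' @export
murmur_confusion <- function(predicted, truth) {
  p <- factor(as.character(predicted), levels = MURMUR_CLASSES)
  t <- factor(as.character(truth), levels = MURMUR_CLASSES)
  if (anyNA(p) || anyNA(t)) stop("labels must be present/unknown/absent")
  m <- table(predicted = p, truth = t)
  structure(unclass(m), class = "murmur_confusion")
}

as_confusion <- function(cm) {
  cm <- unclass(as.matrix(cm))
  stopifnot(nrow(cm) == 3, ncol(cm) == 3, all(cm >= 0))
  dimnames(cm) <- list(predicted = MURMUR_CLASSES, truth = MURMUR_CLASSES)
  cm
}

#' Class-weighted accuracy for the murmur task
#'
#' Correct predictions are weighted by true class: 5 for murmur present, 3
#' for unknown, 1 for absent, rewarding sensitivity to murmurs and honest
#' abstention over bulk accuracy on the prevalent absent class.
#'
#' @param cm A 3x3 confusion matrix (predicted x true, order
#'   present/unknown/absent).
#' @param weights Per-true-class weights.
#' @return Weighted accuracy in \[0, 1\].
#' @export
weighted_accuracy <- function(cm, weights = c(5, 3, 1)) {
  cm <- as_confusion(cm)
  n_true <- colSums(cm)
  if (sum(cm) == 0) stop("empty confusion matrix")
  sum(weights * diag(cm)) / sum(weights * n_true)
}

#' Per-class sensitivity, PPV and F1 for the murmur task
#'
#' Sensitivity (recall) is correct / true count per class, PPV (precision)
#' correct / predicted count, F1 their harmonic mean.  Degenerate
#' denominators give `NA` (reported as undefined, never 0) and are excluded
#' from the macro F1 with a warning.
#'
#' @inheritParams weighted_accuracy
#' @return Tibble with one row per class: `class`, `n_true`, `sensitivity`,
#'   `ppv`, `f1`.
#' @export
per_class_stats <- function(cm) {
  cm <- as_confusion(cm)
  n_true <- colSums(cm)
  n_pred <- rowSums(cm)
  correct <- diag(cm)
  sens <- ifelse(n_true > 0, correct / n_true, NA_real_)
  ppv <- ifelse(n_pred > 0, correct / n_pred, NA_real_)
  f1 <- ifelse(!is.na(sens) & !is.na(ppv) & (sens + ppv) > 0,
               2 * sens * ppv / (sens + ppv), NA_real_)
  if (anyNA(f1)) warning("undefined per-class statistic (empty denominator)")
  tibble::tibble(class = MURMUR_CLASSES, n_true = as.integer(n_true),
                 sensitivity = unname(sens), ppv = unname(ppv),
                 f1 = unname(f1))
}

#' One-row summary of the murmur confusion matrix
#'
#' @inheritParams weighted_accuracy
#' @return Tibble: `weighted_accuracy`, `micro_accuracy` (trace / total),
#'   `macro_f1` (unweighted mean of defined per-class F1), `n`.
#' @export
confusion_summary <- function(cm) {
  cm <- as_confusion(cm)
  stats <- suppressWarnings(per_class_stats(cm))
  tibble::tibble(
    weighted_accuracy = weighted_accuracy(cm),
    micro_accuracy = sum(diag(cm)) / sum(cm),
    macro_f1 = mean(stats$f1, na.rm = TRUE),
    n = sum(cm)
  )
}

#' ROC curve and AUC for a continuous murmur score
#'
#' Sweeps thresholds over the unique score values (a positive call is
#' `score >= threshold`), returns the (sensitivity, specificity) operating
#' points and the trapezoidal AUC; optionally a seeded percentile bootstrap
#' CI on the AUC.
#'
#' @param scores Numeric scores (e.g. per-patient murmur likelihood
#'   `C(M-N)`), higher meaning more murmur-like.
#' @param labels Binary truth (logical, 0/1, or `"present"`/`"absent"`).
#'   Patients labelled unknown must be removed beforehand.
#' @param n_boot Bootstrap iterations for a 95% CI on AUC (0 = none).
#' @param seed Seed for the bootstrap.
#' @return List of class `roc_result`: `points` (tibble threshold /
#'   sensitivity / specificity), `auc`, and `auc_ci` when bootstrapped.
#' @export
roc_curve <- function(scores, labels, n_boot = 0, seed = 1L) {
  y <- roc_binary(labels)
  if (length(unique(y)) < 2) stop("need both classes for a ROC curve")
  pts <- roc_points(scores, y)
  out <- list(points = pts, auc = roc_auc(pts))
  if (n_boot > 0) {
    set.seed(seed)
    n <- length(y)
    aucs <- vapply(seq_len(n_boot), function(i) {
      idx <- sample(n, replace = TRUE)
      if (length(unique(y[idx])) < 2) return(NA_real_)
      roc_auc(roc_points(scores[idx], y[idx]))
    }, 0)
    out$auc_ci <- unname(quantile(aucs, c(0.025, 0.975), na.rm = TRUE))
  }
  structure(out, class = "roc_result")
}

roc_binary <- function(labels) {
  if (is.logical(labels)) return(as.integer(labels))
  if (is.numeric(labels)) return(as.integer(labels != 0))
  x <- tolower(as.character(labels))
  if (any(x == "unknown")) stop("remove 'unknown' patients before ROC analysis")
  as.integer(x %in% c("present", "abnormal", "1", "true", "murmur"))
}

roc_points <- function(scores, y) {
  thr <- c(sort(unique(scores), decreasing = TRUE), Inf)
  thr <- sort(thr, decreasing = TRUE) # Inf first: no positive calls
  np <- sum(y == 1); nn <- sum(y == 0)
  sens <- vapply(thr, function(h) sum(scores >= h & y == 1) / np, 0)
  spec <- vapply(thr, function(h) sum(scores < h & y == 0) / nn, 0)
  tibble::tibble(threshold = thr, sensitivity = sens, specificity = spec)
}

roc_auc <- function(pts) {
  fpr <- 1 - pts$specificity
  ord <- order(fpr, pts$sensitivity)
  x <- c(0, fpr[ord], 1)
  yv <- c(0, pts$sensitivity[ord], 1)
  sum(diff(x) * (head(yv, -1) + yv[-1]) / 2)
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.3f%s (%d operating points)\n", x$auc,
              if (!is.null(x$auc_ci)) {
                sprintf(" [95%% CI %.3f-%.3f]", x$auc_ci[1], x$auc_ci[2])
              } else "",
              nrow(x$points)))
  invisible(x)
}

#' Youden's J index
#'
#' `sensitivity + specificity - 1`; zero for any classifier on the ROC
#' diagonal.
#'
#' @param sensitivity,specificity Fractions in \[0, 1\].
#' @return The index.
#' @export
youden <- function(sensitivity, specificity) {
  stopifnot(all(sensitivity >= 0 & sensitivity <= 1),
            all(specificity >= 0 & specificity <= 1))
  sensitivity + specificity - 1
}

#' Reliability (calibration) bins for a murmur score
#'
#' Splits the score range into equal-width bins and reports, per non-empty
#' bin, the mean score and the relative frequency of true murmurs — the
#' data behind a reliability diagram.
#'
#' @inheritParams roc_curve
#' @param n_bins Number of equal-width bins (>= 2).
#' @return Tibble: `bin`, `mid`, `mean_score`, `frequency`, `n`.
#' @export
reliability_bins <- function(scores, labels, n_bins = 10) {
  stopifnot(n_bins >= 2)
  y <- roc_binary(labels)
  rng <- range(scores)
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  bin <- pmin(findInterval(scores, edges, rightmost.closed = TRUE), n_bins)
  tibble::tibble(scores = scores, y = y, bin = bin) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(mean_score = mean(scores), frequency = mean(y),
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(mid = (edges[.data$bin] + edges[.data$bin + 1]) / 2,
                  .after = "bin")
}
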