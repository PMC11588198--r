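#' Ordinal age-group coding used by the outcome model
#'
#' @format Character vector, youngest to oldest.
#' @export
AGE_GROUPS <- c("neonate", "infant", "child", "adolescent", "young-adult")

#' Assemble the per-patient outcome feature vector
#'
#' For each of the four standard auscultation sites the murmur likelihood
#' `C(M-N)` and signal quality are averaged over that site's recordings;
#' sites without a recording are encoded as missing (`NA`), not zero.
#' Recordings from non-standard sites are pooled into the mitral position
#' with a warning.  The patient's ordinal age group, pregnancy flag and the
#' total recording count complete the vector.
#'
#' @param patient One-row tibble with `patient_id`, `age_group`, `pregnant`.
#' @param decisions Tibble of that patient's per-recording decisions with
#'   columns `site`, `C_MN`, `quality`.
#' @return One-row tibble: `patient_id`, `cmn_AV` .. `cmn_MV`,
#'   `q_AV` .. `q_MV`, `age_group` (integer code), `pregnant` (0/1),
#'   `n_recordings`.
#' @export
build_features <- function(patient, decisions) {
  stopifnot(nrow(decisions) >= 1)
  site <- as.character(decisions$site)
  if (any(!site %in% PCG_SITES)) {
    warning("pooling ", sum(!site %in% PCG_SITES),
            " recording(s) from non-standard sites into MV")
    site[!site %in% PCG_SITES] <- "MV"
  }
  per_site <- function(values) {
    vapply(PCG_SITES, function(s) {
      if (any(site == s)) mean(values[site == s]) else NA_real_
    }, 0)
  }
  cmn <- per_site(decisions$C_MN)
  q <- per_site(decisions$quality)
  out <- tibble::tibble(patient_id = patient$patient_id)
  for (s in PCG_SITES) out[[paste0("cmn_", s)]] <- cmn[[s]]
  for (s in PCG_SITES) out[[paste0("q_", s)]] <- q[[s]]
  out$age_group <- match(as.character(patient$age_group), AGE_GROUPS)
  out$pregnant <- as.integer(isTRUE(patient$pregnant) || identical(patient$pregnant, 1L))
  out$n_recordings <- nrow(decisions)
  out
}

#' Outcome feature table for a cohort
#'
#' @param patients Tibble with one row per patient (`patient_id`,
#'   `age_group`, `pregnant`, optionally `outcome`).
#' @param decisions Tibble of per-recording decisions with `patient_id`,
#'   `site`, `C_MN`, `quality`.
#' @return Tibble with one row per patient; `outcome` carried through when
#'   present.
#' @export
build_outcome_features <- function(patients, decisions) {
  rows <- lapply(seq_len(nrow(patients)), function(i) {
    p <- patients[i, ]
    d <- decisions[decisions$patient_id == p$patient_id, , drop = FALSE]
    f <- build_features(p, d)
    if ("outcome" %in% names(patients)) f$outcome <- p$outcome
    f
  })
  dplyr::bind_rows(rows)
}

outcome_feature_names <- function() {
  c(paste0("cmn_", PCG_SITES), paste0("q_", PCG_SITES),
    "age_group", "pregnant", "n_recordings")
}

#' Train the gradient-boosted clinical-outcome classifier
#'
#' Boosted decision trees (binary logistic objective) of maximum depth 9,
#' with abnormal examples weighted 1.8 against 1 for normal to prioritise
#' sensitivity.  Missing site features are handled natively by the tree
#' learner.  A validation fold (20% of patients) drives early stopping.
#'
#' @param features Tibble from [build_outcome_features()] including an
#'   `outcome` column (`"normal"`/`"abnormal"` or 0/1).
#' @param max_depth Tree depth (default 9).
#' @param abnormal_weight Class weight for abnormal examples (default 1.8).
#' @param nrounds,learning_rate Boosting iterations and shrinkage.
#' @param threshold Decision threshold stored with the model (default
#'   0.4738).
#' @param seed Seed for the validation split and the learner.
#' @return An `outcome_model`: list with the fitted booster, feature names,
#'   threshold and training parameters.
#' @export
train_outcome <- function(features, max_depth = 9, abnormal_weight = 1.8,
                          nrounds = 200, learning_rate = 0.1,
                          threshold = 0.4738, seed = 1L) {
  y <- outcome_to_binary(features$outcome)
  if (length(unique(y)) < 2) stop("need both outcome classes to train")
  fn <- outcome_feature_names()
  X <- as.matrix(features[, fn])
  w <- ifelse(y == 1, abnormal_weight, 1)
  set.seed(seed)
  n <- nrow(X)
  val <- sample(n, max(2L, round(0.2 * n)))
  # guard: both classes in the validation fold, else early stopping is blind
  if (length(unique(y[val])) < 2) val <- c(val, which(y != y[val[1]])[1])
  tr <- setdiff(seq_len(n), val)
  dtr <- xgboost::xgb.DMatrix(X[tr, , drop = FALSE], label = y[tr],
                              weight = w[tr], missing = NA)
  dval <- xgboost::xgb.DMatrix(X[val, , drop = FALSE], label = y[val],
                               weight = w[val], missing = NA)
  booster <- xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = max_depth,
                  eta = learning_rate, nthread = 1, seed = seed,
                  eval_metric = "logloss"),
    data = dtr, nrounds = nrounds,
    evals = list(val = dval),
    early_stopping_rounds = 20, verbose = 0
  )
  structure(
    list(booster = booster, feature_names = fn, threshold = threshold,
         params = list(max_depth = max_depth, abnormal_weight = abnormal_weight,
                       nrounds = nrounds, learning_rate = learning_rate,
                       seed = seed)),
    class = "outcome_model"
  )
}

outcome_to_binary <- function(outcome) {
  if (is.numeric(outcome)) return(as.integer(outcome != 0))
  as.integer(tolower(as.character(outcome)) %in% c("abnormal", "1", "true"))
}

#' Predict clinical outcome for patients
#'
#' @param model An `outcome_model`.
#' @param features Tibble from [build_outcome_features()].
#' @param threshold Probability threshold for calling `abnormal`; defaults
#'   to the threshold stored in the model (0.4738).
#' @return Tibble: `patient_id` (if present), `probability`, `label`
#'   (`"abnormal"` iff probability >= threshold).
#' @export
predict_outcome <- function(model, features, threshold = NULL) {
  stopifnot(inherits(model, "outcome_model"))
  threshold <- threshold %||% model$threshold
  X <- as.matrix(features[, model$feature_names])
  p <- predict(model$booster, xgboost::xgb.DMatrix(X, missing = NA))
  out <- tibble::tibble(
    probability = as.numeric(p),
    label = factor(ifelse(p >= threshold, "abnormal", "normal"),
                   levels = c("normal", "abnormal"))
  )
  if ("patient_id" %in% names(features)) {
    out <- dplyr::bind_cols(tibble::tibble(patient_id = features$patient_id), out)
  }
  out
}

#' @export
print.outcome_model <- function(x, ...) {
  cat(sprintf(
    "<outcome_model> boosted trees, depth %d, abnormal weight %.1f, %d rounds (best %s), threshold %.4f\n",
    x$params$max_depth, x$params$abnormal_weight, x$params$nrounds,
    xgboost::xgb.attributes(x$booster)$best_iteration %||% "all",
    x$threshold))
  invisible(x)
}
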