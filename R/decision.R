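#' Patient-level murmur classification
#'
#' Aggregates per-recording parallel-HSMM decisions into one of `present`,
#' `unknown`, `absent`: a murmur in *any* recording yields `present`;
#' otherwise, if the aggregated signal quality (by default the mean of the
#' chosen-model confidences, switchable to the minimum) falls below
#' `quality_threshold` the patient cannot be confidently screened and is
#' `unknown`; otherwise `absent`.
#'
#' @param decisions Tibble of per-recording decisions with at least columns
#'   `murmur` (logical), `quality` and `C_MN` (e.g. rows from
#'   [detect_murmur()] or [segment_cohort()]).
#' @param quality_threshold Quality threshold below which an all-normal
#'   patient is labelled `unknown` (default 0.65).
#' @param aggregate `"mean"` (default) or `"min"` across recordings.
#' @return One-row tibble: `label`, `quality` (aggregate), `max_C_MN`,
#'   `n_recordings`.
#' @export
classify_patient <- function(decisions, quality_threshold = 0.65,
                             aggregate = c("mean", "min")) {
  aggregate <- match.arg(aggregate)
  if (nrow(decisions) == 0) stop("need at least one recording decision")
  agg_q <- if (aggregate == "mean") mean(decisions$quality) else min(decisions$quality)
  label <- if (any(decisions$murmur)) {
    "present"
  } else if (agg_q < quality_threshold) {
    "unknown"
  } else {
    "absent"
  }
  tibble::tibble(
    label = factor(label, levels = c("present", "unknown", "absent")),
    quality = agg_q,
    max_C_MN = max(decisions$C_MN),
    n_recordings = nrow(decisions)
  )
}

#' Patient-level murmur labels for a whole cohort
#'
#' Groups per-recording decisions by `patient_id` and applies
#' [classify_patient()] to each group.
#'
#' @param decisions Tibble with a `patient_id` column plus the columns
#'   required by [classify_patient()].
#' @inheritParams classify_patient
#' @return Tibble with one row per patient.
#' @export
classify_patients <- function(decisions, quality_threshold = 0.65,
                              aggregate = "mean") {
  decisions |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::group_modify(~ classify_patient(.x, quality_threshold, aggregate)) |>
    dplyr::ungroup()
}
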