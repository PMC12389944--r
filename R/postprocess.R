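# Temporal smoothing of epoch predictions and duration estimation.
#
# Epoch predictions arrive on a 2.5 s grid. A 10 s sliding window (4
# epochs), stepping one epoch at a time, repairs isolated misclassifications
# by flipping the minority value to the majority — but only at a boundary,
# i.e. when the last value in the window differs from the first value just
# outside it. The predicted session duration is the longest run of positive
# predictions times the hop.

#' Majority-flip smoothing of a binary prediction sequence
#'
#' Scans windows of `window_s / hop_s` consecutive predictions left to right
#' with a step of one epoch, modifying in place (later windows see earlier
#' flips). For each window whose last element differs from the first element
#' outside the window (the boundary condition, applied symmetrically for
#' 0-to-1 and 1-to-0 boundaries), if one value holds a strict majority, all
#' minority values in the window are flipped to it. Exact ties are left
#' unchanged, as both values then satisfy "50% or more" and no majority
#' exists. The final window has no outside element and is skipped.
#'
#' @param predictions integer vector of 0/1 epoch predictions, in time order.
#' @param window_s smoothing window in seconds (default 10).
#' @param hop_s epoch hop in seconds (default 2.5); must divide `window_s`.
#' @return smoothed integer vector, same length.
#' @export
#' @examples
#' flip_misclassified(c(1, 0, 1, 1, 0)) # repaired to 1 1 1 1 0
flip_misclassified <- function(predictions, window_s = 10, hop_s = 2.5) {
  p <- as.integer(predictions)
  if (any(!p %in% c(0L, 1L))) abort("predictions must be 0/1.")
  w <- window_s / hop_s
  if (abs(w - round(w)) > 1e-9) abort("hop_s must divide window_s.")
  w <- as.integer(round(w))
  n <- length(p)
  if (n <= w) return(p)
  for (i in seq_len(n - w)) {           # last full window with an outside element
    win <- i:(i + w - 1)
    if (p[i + w - 1] == p[i + w]) next  # no boundary after this window
    ones <- sum(p[win])
    if (2 * ones > w) {
      p[win] <- 1L
    } else if (2 * ones < w) {
      p[win] <- 0L
    }                                   # exact tie: leave unchanged
  }
  p
}

#' Longest positive run as a duration
#'
#' Length of the longest run of consecutive 1s times the epoch hop; 0 when
#' there are no positive predictions. This is the predicted suppression
#' duration for one (session, channel) prediction sequence.
#'
#' @param predictions integer vector of 0/1 predictions.
#' @param hop_s epoch hop in seconds.
#' @return duration in seconds.
#' @export
longest_run_duration <- function(predictions, hop_s = 2.5) {
  p <- as.integer(predictions)
  if (length(p) == 0 || !any(p == 1L)) return(0)
  r <- rle(p)
  max(r$lengths[r$values == 1L]) * hop_s
}

#' Per-patient duration report
#'
#' Averages predicted durations over all (session, channel) sequences of each
#' patient, averages the annotated true durations over the same sessions, and
#' reports the absolute offset — the layout of a per-patient duration table.
#'
#' @param durations tibble with columns `patient_id`, `session_id`,
#'   `channel`, `predicted_duration_s`, `true_duration_s` (one row per
#'   session x channel; `true_duration_s` identical across channels of a
#'   session).
#' @return tibble with one row per patient: `patient_id`,
#'   `predicted_duration_s`, `true_duration_s`, `offset_s`.
#' @export
patient_duration <- function(durations) {
  if (nrow(durations) == 0) abort("no duration rows supplied.")
  durations |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(
      predicted_duration_s = mean(.data$predicted_duration_s),
      true_duration_s = mean(.data$true_duration_s),
      .groups = "drop"
    ) |>
    dplyr::mutate(offset_s = abs(.data$predicted_duration_s - .data$true_duration_s))
}

#' Cohort duration-offset table
#'
#' Emits the per-patient rows plus the cohort average offset, defined as the
#' arithmetic mean of the per-row offsets (sum of offsets divided by the
#' number of rows).
#'
#' @param report per-patient tibble as from [patient_duration()], or any
#'   tibble with `predicted_duration_s` and `true_duration_s` columns (the
#'   offset is recomputed).
#' @return list with `table` (per-patient tibble including `offset_s`) and
#'   `average_offset_s`.
#' @export
cohort_offset_table <- function(report) {
  if (nrow(report) == 0) abort("empty duration report.")
  tab <- report |>
    dplyr::mutate(offset_s = abs(.data$predicted_duration_s - .data$true_duration_s))
  list(table = tab, average_offset_s = mean(tab$offset_s))
}
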