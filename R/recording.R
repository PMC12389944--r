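#' Construct an EEG recording object
#'
#' An `eeg_recording` bundles a multichannel EEG signal (microvolts) with its
#' sample rate, identity, and interval annotations. It is the unit that flows
#' through re-referencing, seizure excision, preprocessing and feature
#' extraction.
#'
#' @param signal numeric matrix, channels x samples, in microvolts.
#' @param sample_rate sampling rate in Hz (positive).
#' @param channels character vector of channel labels, one per signal row.
#' @param patient_id,session_id identity strings.
#' @param annotations tibble of interval annotations with columns
#'   `start_s`, `end_s`, `label` (`"seizure"` or `"pges"`), times in seconds
#'   from recording start, half-open `[start_s, end_s)`.
#' @param cuts numeric vector of splice points (seconds) left behind by
#'   [excise_intervals()]; epochs are never formed across a cut.
#'
#' @return An object of class `eeg_recording`.
#' @export
#' @examples
#' rec <- eeg_recording(matrix(rnorm(414), 2), 207, c("FP2", "T8"))
#' rec
eeg_recording <- function(signal, sample_rate, channels,
                          patient_id = "P00", session_id = "S00",
                          annotations = empty_annotations(),
                          cuts = numeric(0)) {
  if (!is.matrix(signal)) signal <- matrix(signal, nrow = 1)
  if (!is.numeric(sample_rate) || length(sample_rate) != 1 || sample_rate <= 0) {
    abort("`sample_rate` must be a single positive number (Hz).")
  }
  channels <- as.character(channels)
  if (nrow(signal) != length(channels)) {
    abort(sprintf(
      "signal has %d rows but %d channel labels were given.",
      nrow(signal), length(channels)
    ))
  }
  annotations <- validate_annotations(annotations)
  dur <- ncol(signal) / sample_rate
  if (nrow(annotations) > 0 &&
      any(annotations$start_s < 0 | annotations$end_s > dur + 1e-9)) {
    abort("annotation intervals must lie within [0, duration] of the recording.")
  }
  structure(
    list(
      patient_id = as.character(patient_id),
      session_id = as.character(session_id),
      sample_rate = as.numeric(sample_rate),
      channels = channels,
      signal = signal,
      annotations = annotations,
      cuts = as.numeric(cuts)
    ),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording> %s/%s: %d channel(s) [%s], %.1f s @ %g Hz, %d annotation(s)\n",
    x$patient_id, x$session_id, length(x$channels),
    paste(x$channels, collapse = ", "),
    recording_duration(x), x$sample_rate, nrow(x$annotations)
  ))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec an `eeg_recording`.
#' @return length in seconds.
#' @export
recording_duration <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  ncol(rec$signal) / rec$sample_rate
}

#' An empty annotation table
#' @return zero-row annotation tibble.
#' @export
empty_annotations <- function() {
  tibble(start_s = numeric(0), end_s = numeric(0), label = character(0))
}

annotation_labels <- c("seizure", "pges")

validate_annotations <- function(ann) {
  ann <- as_tibble(ann)
  needed <- c("start_s", "end_s", "label")
  if (!all(needed %in% names(ann))) {
    abort("annotations need columns start_s, end_s, label.")
  }
  ann$start_s <- as.numeric(ann$start_s)
  ann$end_s <- as.numeric(ann$end_s)
  ann$label <- as.character(ann$label)
  if (nrow(ann) > 0) {
    if (any(!ann$label %in% annotation_labels)) {
      abort(sprintf(
        "annotation labels must be one of: %s.",
        paste(annotation_labels, collapse = ", ")
      ))
    }
    if (any(ann$start_s >= ann$end_s)) {
      abort("annotation intervals must satisfy start_s < end_s.")
    }
  }
  ann[, needed]
}

# Merge overlapping/adjacent intervals (matrix of start, end rows) into a
# disjoint, sorted set. Half-open convention: touching intervals merge.
merge_intervals <- function(starts, ends) {
  if (length(starts) == 0) {
    return(list(start = numeric(0), end = numeric(0)))
  }
  o <- order(starts)
  starts <- starts[o]
  ends <- ends[o]
  ms <- starts[1]
  me <- ends[1]
  out_s <- numeric(0)
  out_e <- numeric(0)
  for (i in seq_along(starts)[-1]) {
    if (starts[i] <= me) {
      me <- max(me, ends[i])
    } else {
      out_s <- c(out_s, ms)
      out_e <- c(out_e, me)
      ms <- starts[i]
      me <- ends[i]
    }
  }
  list(start = c(out_s, ms), end = c(out_e, me))
}

# Total overlap (seconds) between [a0, a1) and a set of disjoint intervals.
interval_overlap <- function(a0, a1, starts, ends) {
  if (length(starts) == 0) return(0)
  sum(pmax(0, pmin(a1, ends) - pmax(a0, starts)))
}
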