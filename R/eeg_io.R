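# Recording input/output, bipolar montage, and seizure-segment excision.

# 10-20 electrode naming changed in the modified combinatorial system; both
# conventions occur in annotated archives, so channel lookup accepts either.
channel_aliases <- c(
  T3 = "T7", T4 = "T8", T5 = "P7", T6 = "P8"
)

canonical_channel <- function(label) {
  lab <- toupper(trimws(label))
  ifelse(lab %in% names(channel_aliases), unname(channel_aliases[lab]), lab)
}

match_channel <- function(rec, label) {
  want <- canonical_channel(label)
  have <- canonical_channel(rec$channels)
  i <- match(want, have)
  if (is.na(i)) {
    abort(sprintf(
      "channel '%s' not found; recording has: %s.",
      label, paste(rec$channels, collapse = ", ")
    ), class = "pgesr_channel_error")
  }
  i
}

#' Read an EEG recording from disk
#'
#' Reads an EDF file or the plain tabular fallback format into an
#' [eeg_recording()]. Signals are converted to microvolts. If an annotation
#' sidecar `<stem>.annotations.csv` exists next to the file it is loaded
#' automatically.
#'
#' The tabular format is: line 1 `sample_rate=<Hz> unit=<uV|mV|V>`, line 2
#' comma-separated channel labels, then one comma-separated row of samples
#' per time point.
#'
#' @param path path to an `.edf` or tabular (`.csv`/`.txt`) file.
#' @param format `"auto"` (by extension), `"edf"`, or `"tabular"`.
#' @param patient_id,session_id identity strings; by default parsed from a
#'   `<patient>_<session>` file-name stem.
#' @return an [eeg_recording()].
#' @export
read_recording <- function(path, format = c("auto", "edf", "tabular"),
                           patient_id = NULL, session_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "tabular"
  }
  stem <- sub("\\.[^.]*$", "", basename(path))
  parts <- strsplit(stem, "_", fixed = TRUE)[[1]]
  patient_id <- patient_id %||% parts[1]
  session_id <- session_id %||% (if (length(parts) > 1) parts[2] else "S01")

  raw <- if (format == "edf") read_edf(path) else read_tabular(path)

  ann_path <- paste0(sub("\\.[^.]*$", "", path), ".annotations.csv")
  ann <- if (file.exists(ann_path)) {
    read_annotations(ann_path, patient_id = patient_id, session_id = session_id)
  } else {
    empty_annotations()
  }

  eeg_recording(raw$signal, raw$sample_rate, raw$channels,
                patient_id = patient_id, session_id = session_id,
                annotations = ann)
}

read_tabular <- function(path) {
  lines <- readLines(path, n = 2)
  hdr <- lines[1]
  get_kv <- function(key) {
    m <- regmatches(hdr, regexec(paste0(key, "=([^ ,;\t]+)"), hdr))[[1]]
    if (length(m) < 2) NULL else m[2]
  }
  rate <- suppressWarnings(as.numeric(get_kv("sample_rate")))
  if (is.null(get_kv("sample_rate")) || is.na(rate) || rate <= 0) {
    abort("tabular recording lacks a valid 'sample_rate=' header field.",
          class = "pgesr_unit_error")
  }
  unit <- get_kv("unit")
  if (is.null(unit)) {
    abort("tabular recording lacks a 'unit=' header field (uV, mV or V).",
          class = "pgesr_unit_error")
  }
  fac <- edf_unit_factor(unit)
  if (is.null(fac)) {
    abort(sprintf("unit '%s' is not convertible to microvolts.", unit),
          class = "pgesr_unit_error")
  }
  channels <- trimws(strsplit(lines[2], ",", fixed = TRUE)[[1]])
  dat <- utils::read.csv(path, skip = 1, header = TRUE, check.names = FALSE)
  list(
    signal = t(as.matrix(dat)) * fac,
    sample_rate = rate,
    channels = channels
  )
}

#' Write a recording to disk
#'
#' Writes EDF (for whole-second, integer-rate recordings) or the tabular
#' fallback, plus the annotation sidecar when annotations are present.
#'
#' @param rec an [eeg_recording()].
#' @param path output path; `.edf` selects EDF, anything else tabular.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (grepl("\\.edf$", path, ignore.case = TRUE)) {
    write_edf(rec, path)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("sample_rate=%g unit=uV", rec$sample_rate), con)
    writeLines(paste(rec$channels, collapse = ","), con)
    utils::write.table(
      t(rec$signal), con, sep = ",", row.names = FALSE, col.names = FALSE
    )
  }
  if (nrow(rec$annotations) > 0) {
    write_annotations(
      dplyr::mutate(rec$annotations,
                    patient_id = rec$patient_id,
                    session_id = rec$session_id),
      paste0(sub("\\.[^.]*$", "", path), ".annotations.csv")
    )
  }
  invisible(path)
}

#' Read or write an interval-annotation sidecar
#'
#' Annotation CSVs have columns `patient_id`, `session_id`, `start_s`,
#' `end_s`, `label`; times are seconds from recording start and intervals are
#' half-open `[start_s, end_s)`.
#'
#' @param path CSV path.
#' @param patient_id,session_id optional filters; rows for other sessions are
#'   dropped when given.
#' @return tibble with `start_s`, `end_s`, `label` (and identity columns if
#'   present in the file).
#' @export
read_annotations <- function(path, patient_id = NULL, session_id = NULL) {
  ann <- as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  if (!is.null(patient_id) && "patient_id" %in% names(ann)) {
    ann <- dplyr::filter(ann, .data$patient_id == .env$patient_id)
  }
  if (!is.null(session_id) && "session_id" %in% names(ann)) {
    ann <- dplyr::filter(ann, .data$session_id == .env$session_id)
  }
  validate_annotations(ann)
}

#' @rdname read_annotations
#' @param ann annotation tibble including identity columns.
#' @export
write_annotations <- function(ann, path) {
  cols <- intersect(
    c("patient_id", "session_id", "start_s", "end_s", "label"), names(ann)
  )
  utils::write.csv(ann[, cols], path, row.names = FALSE)
  invisible(path)
}

#' Build a bipolar montage
#'
#' Forms anode-minus-reference difference channels, the montage produced by a
#' two-channel subcutaneous device (e.g. FP2-F8, T8-F8). Any signal common to
#' all electrodes (such as an average-reference offset) cancels exactly.
#' Channel lookup accepts old/new 10-20 synonyms (T4 for T8, T6 for P8, ...).
#'
#' @param rec an [eeg_recording()].
#' @param anodes character vector of anode labels.
#' @param reference single reference label.
#' @return an [eeg_recording()] with one `ANODE-REF` channel per anode;
#'   annotations preserved.
#' @export
#' @examples
#' rec <- eeg_recording(matrix(rnorm(3 * 100), 3), 100, c("FP2", "T8", "F8"))
#' make_bipolar(rec, c("FP2", "T4"), "F8")$channels
make_bipolar <- function(rec, anodes, reference) {
  stopifnot(inherits(rec, "eeg_recording"))
  ref_i <- match_channel(rec, reference)
  anode_i <- vapply(anodes, function(a) match_channel(rec, a), 1L)
  sig <- rec$signal[anode_i, , drop = FALSE] -
    matrix(rec$signal[ref_i, ], nrow = length(anode_i),
           ncol = ncol(rec$signal), byrow = TRUE)
  eeg_recording(
    sig, rec$sample_rate,
    paste0(canonical_channel(anodes), "-", canonical_channel(reference)),
    patient_id = rec$patient_id, session_id = rec$session_id,
    annotations = rec$annotations, cuts = rec$cuts
  )
}

#' Remove annotated intervals from a recording
#'
#' Cuts out all samples inside intervals carrying `label` (overlapping
#' intervals are merged first) and splices the remainder together. Remaining
#' annotations are re-timed to the new concatenated timeline; annotations of
#' the excised label are dropped. Each splice point is recorded in the
#' returned recording's `cuts` so that downstream epoching never forms a
#' window across a splice. The typical use is removing clinician-marked
#' seizure segments before preprocessing.
#'
#' @param rec an [eeg_recording()].
#' @param label `"seizure"` or `"pges"`.
#' @return a shorter [eeg_recording()].
#' @export
excise_intervals <- function(rec, label = "seizure") {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!label %in% annotation_labels) {
    abort(sprintf("label must be one of: %s.", paste(annotation_labels, collapse = ", ")))
  }
  fs <- rec$sample_rate
  n <- ncol(rec$signal)
  dur <- n / fs
  target <- rec$annotations[rec$annotations$label == label, ]
  if (nrow(target) == 0) return(rec)

  m <- merge_intervals(pmax(target$start_s, 0), pmin(target$end_s, dur))
  # sample-index arithmetic keeps counts exact: [i0, i1) half-open
  i0 <- pmin(pmax(round(m$start * fs), 0), n)
  i1 <- pmin(pmax(round(m$end * fs), 0), n)

  keep <- rep(TRUE, n)
  for (k in seq_along(i0)) if (i1[k] > i0[k]) keep[(i0[k] + 1):i1[k]] <- FALSE
  if (!any(keep)) abort("excision removes the entire recording.")

  # kept segments in original sample indices (half-open)
  runs <- rle(keep)
  stops <- cumsum(runs$lengths)
  starts <- stops - runs$lengths + 1
  seg <- which(runs$values)
  seg_a <- starts[seg] - 1   # 0-based start sample
  seg_b <- stops[seg]        # 0-based end sample (exclusive)
  new_off <- cumsum(c(0, (seg_b - seg_a)[-length(seg)]))

  # re-time the other annotations: clip to kept segments, map, merge pieces
  others <- rec$annotations[rec$annotations$label != label, ]
  new_ann <- empty_annotations()
  if (nrow(others) > 0) {
    pieces <- purrr::pmap_dfr(others, function(start_s, end_s, label) {
      a0 <- round(start_s * fs)
      a1 <- round(end_s * fs)
      lo <- pmax(a0, seg_a)
      hi <- pmin(a1, seg_b)
      ok <- hi > lo
      if (!any(ok)) return(empty_annotations())
      tibble(
        start_s = (new_off[ok] + (lo[ok] - seg_a[ok])) / fs,
        end_s = (new_off[ok] + (hi[ok] - seg_a[ok])) / fs,
        label = label
      )
    })
    if (nrow(pieces) > 0) {
      new_ann <- pieces |>
        dplyr::group_by(.data$label) |>
        dplyr::reframe(as_tibble(merge_intervals(.data$start_s, .data$end_s))) |>
        dplyr::transmute(start_s = .data$start, end_s = .data$end,
                         label = .data$label)
    }
  }

  # splice points in the new timeline (interior boundaries between segments),
  # plus any previous cuts re-mapped
  new_cuts <- (new_off + (seg_b - seg_a))[-length(seg)] / fs
  old_cuts_samp <- round(rec$cuts * fs)
  ok <- old_cuts_samp >= seg_a[1]
  mapped_old <- vapply(rec$cuts, function(cc) {
    cs <- round(cc * fs)
    j <- which(cs >= seg_a & cs <= seg_b)
    if (length(j) == 0) return(NA_real_)
    (new_off[j[1]] + (cs - seg_a[j[1]])) / fs
  }, 1.0)
  new_cuts <- sort(unique(c(new_cuts, mapped_old[!is.na(mapped_old)])))

  eeg_recording(
    rec$signal[, keep, drop = FALSE], fs, rec$channels,
    patient_id = rec$patient_id, session_id = rec$session_id,
    annotations = new_ann, cuts = new_cuts
  )
}
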