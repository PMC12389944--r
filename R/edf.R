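# Minimal EDF (European Data Format) reader/writer.
#
# Only the plain EDF profile needed here is supported: identical sample rate
# across signals, 16-bit samples, physical dimension restricted to voltage
# units convertible to microvolts. EDF+ annotation channels are not parsed;
# interval annotations travel in a CSV sidecar (see read_annotations()).

edf_field <- function(con, n) trimws(readChar(con, n, useBytes = TRUE))

edf_unit_factor <- function(dim) {
  # conversion to microvolts
  switch(tolower(trimws(dim)),
    "uv" = 1, "µv" = 1, "microv" = 1,
    "mv" = 1e3,
    "v" = 1e6,
    NULL
  )
}

#' Read an EDF file
#'
#' Reads a plain EDF file into channel x sample matrix form, converting
#' physical values to microvolts. All signals must share one sample rate.
#'
#' @param path path to an `.edf` file.
#' @return list with `signal` (channels x samples matrix, microvolts),
#'   `sample_rate` (Hz) and `channels` (labels).
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  version <- edf_field(con, 8)
  if (!identical(version, "0")) abort("not an EDF file (bad version field).")
  edf_field(con, 80) # patient
  edf_field(con, 80) # recording
  edf_field(con, 8)  # date
  edf_field(con, 8)  # time
  edf_field(con, 8)  # header bytes
  edf_field(con, 44) # reserved
  n_rec <- as.integer(edf_field(con, 8))
  rec_dur <- as.numeric(edf_field(con, 8))
  ns <- as.integer(edf_field(con, 4))
  if (is.na(ns) || ns < 1) abort("EDF header declares no signals.")

  labels <- vapply(seq_len(ns), function(i) edf_field(con, 16), "")
  for (i in seq_len(ns)) edf_field(con, 80) # transducer
  dims <- vapply(seq_len(ns), function(i) edf_field(con, 8), "")
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) edf_field(con, 8), ""))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) edf_field(con, 8), ""))
  dmin_ <- as.numeric(vapply(seq_len(ns), function(i) edf_field(con, 8), ""))
  dmax_ <- as.numeric(vapply(seq_len(ns), function(i) edf_field(con, 8), ""))
  for (i in seq_len(ns)) edf_field(con, 80) # prefiltering
  spr <- as.integer(vapply(seq_len(ns), function(i) edf_field(con, 8), ""))
  for (i in seq_len(ns)) edf_field(con, 32) # reserved

  if (length(unique(spr)) != 1) {
    abort("EDF signals with differing sample rates are not supported.")
  }
  if (is.na(rec_dur) || rec_dur <= 0) abort("EDF file lacks a valid record duration.")
  sample_rate <- spr[1] / rec_dur

  factors <- lapply(dims, edf_unit_factor)
  bad <- vapply(factors, is.null, TRUE)
  if (any(bad)) {
    abort(sprintf(
      "EDF physical dimension(s) %s not convertible to microvolts.",
      paste(unique(dims[bad]), collapse = ", ")
    ))
  }
  gain <- (pmax_ - pmin_) / (dmax_ - dmin_)

  n_total <- n_rec * spr[1]
  sig <- matrix(0, nrow = ns, ncol = n_total)
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      raw <- readBin(con, "integer", n = spr[1], size = 2,
                     signed = TRUE, endian = "little")
      phys <- (raw - dmin_[s]) * gain[s] + pmin_[s]
      sig[s, ((r - 1) * spr[1] + 1):(r * spr[1])] <- phys * factors[[s]]
    }
  }
  list(signal = sig, sample_rate = sample_rate, channels = labels)
}

edf_pad <- function(x, n) {
  x <- as.character(x)
  if (nchar(x) > n) x <- substr(x, 1, n)
  formatC(x, width = n, flag = "-")
}

edf_num <- function(x, n) {
  s <- formatC(x, format = "fg", width = 1, digits = 7)
  if (nchar(s) > n) s <- substr(s, 1, n)
  edf_pad(s, n)
}

#' Write an EDF file
#'
#' Writes a channels x samples microvolt matrix as plain EDF with one-second
#' data records. The signal is truncated to a whole number of seconds (with a
#' warning) because EDF stores complete records only; `sample_rate` must be a
#' whole number per second.
#'
#' @param rec an [eeg_recording()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  spr <- rec$sample_rate
  if (abs(spr - round(spr)) > 1e-9) {
    abort("EDF writer requires an integer number of samples per second.")
  }
  spr <- as.integer(round(spr))
  n_rec <- ncol(rec$signal) %/% spr
  if (n_rec < 1) abort("recording shorter than one EDF record (1 s).")
  if (n_rec * spr < ncol(rec$signal)) {
    warn(sprintf(
      "truncating %d trailing sample(s) to fit whole 1 s EDF records.",
      ncol(rec$signal) - n_rec * spr
    ))
  }
  sig <- rec$signal[, seq_len(n_rec * spr), drop = FALSE]
  ns <- nrow(sig)

  pmin_ <- apply(sig, 1, min)
  pmax_ <- apply(sig, 1, max)
  flat <- pmax_ - pmin_ < 1e-12
  pmin_[flat] <- pmin_[flat] - 1
  pmax_[flat] <- pmax_[flat] + 1
  dmin_ <- -32768
  dmax_ <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  hdr_bytes <- 256 + 256 * ns
  writeChar(paste0(
    edf_pad("0", 8),
    edf_pad(rec$patient_id, 80),
    edf_pad(rec$session_id, 80),
    edf_pad("01.01.00", 8),
    edf_pad("00.00.00", 8),
    edf_pad(hdr_bytes, 8),
    edf_pad("", 44),
    edf_pad(n_rec, 8),
    edf_pad("1", 8),
    edf_pad(ns, 4),
    paste(vapply(rec$channels, edf_pad, "", n = 16), collapse = ""),
    paste(rep(edf_pad("", 80), ns), collapse = ""),
    paste(rep(edf_pad("uV", 8), ns), collapse = ""),
    paste(vapply(pmin_, edf_num, "", n = 8), collapse = ""),
    paste(vapply(pmax_, edf_num, "", n = 8), collapse = ""),
    paste(rep(edf_pad(dmin_, 8), ns), collapse = ""),
    paste(rep(edf_pad(dmax_, 8), ns), collapse = ""),
    paste(rep(edf_pad("", 80), ns), collapse = ""),
    paste(rep(edf_pad(spr, 8), ns), collapse = ""),
    paste(rep(edf_pad("", 32), ns), collapse = "")
  ), con, eos = NULL, useBytes = TRUE)

  # re-read the numeric header fields exactly as a reader will parse them so
  # digitisation uses the stored (string-precision) physical range
  gain <- (as.numeric(vapply(pmax_, edf_num, "", n = 8)) -
             as.numeric(vapply(pmin_, edf_num, "", n = 8))) / (dmax_ - dmin_)
  pmin_stored <- as.numeric(vapply(pmin_, edf_num, "", n = 8))

  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * spr + 1):(r * spr)
    for (s in seq_len(ns)) {
      dig <- round((sig[s, idx] - pmin_stored[s]) / gain[s]) + dmin_
      dig <- pmin(pmax(dig, dmin_), dmax_)
      writeBin(as.integer(dig), con, size = 2, endian = "little")
    }
  }
  invisible(path)
}
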