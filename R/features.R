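# Epoching and the 14-feature vector: five rectified time-domain statistics,
# four absolute and four relative band powers (delta/theta/alpha/beta), and
# the Petrosian fractal dimension.

#' Feature-extraction specification
#'
#' @param window_s epoch length in seconds (default 5).
#' @param hop_s hop between epoch starts in seconds (default 2.5, i.e. 50%
#'   overlap).
#' @param bands named list of `c(low, high)` band edges in Hz; defaults to
#'   delta 0.5-4, theta 4-8, alpha 8-12, beta 12-40.
#' @param label_overlap_fraction fraction of the window that must overlap a
#'   suppression interval for the epoch to be labelled positive (default 0.5).
#' @param welch_seg_s Welch segment length in seconds for PSD estimation.
#' @return a `feature_spec` list.
#' @export
feature_spec <- function(window_s = 5, hop_s = 2.5,
                         bands = list(delta = c(0.5, 4), theta = c(4, 8),
                                      alpha = c(8, 12), beta = c(12, 40)),
                         label_overlap_fraction = 0.5,
                         welch_seg_s = 1) {
  if (!(hop_s > 0 && hop_s <= window_s)) abort("need 0 < hop_s <= window_s.")
  for (b in bands) {
    if (!(length(b) == 2 && b[1] < b[2])) abort("band edges must be increasing pairs.")
  }
  structure(
    list(window_s = window_s, hop_s = hop_s, bands = bands,
         label_overlap_fraction = label_overlap_fraction,
         welch_seg_s = welch_seg_s),
    class = "feature_spec"
  )
}

#' Feature column names, in the fixed extraction order
#' @param spec a [feature_spec()].
#' @return character vector of 14 names.
#' @export
feature_names <- function(spec = feature_spec()) {
  bn <- names(spec$bands)
  c("abs_mean", "abs_sd", "abs_median", "abs_max", "abs_min",
    paste0("bp_", bn), paste0("rel_", bn), "pfd")
}

#' Cut a recording into overlapping epochs
#'
#' Epoch starts are `0, hop_s, 2 hop_s, ...`; a trailing partial window is
#' discarded, and epochs spanning a splice cut-point (left by
#' [excise_intervals()]) are dropped so no window mixes signal across a
#' removed segment.
#'
#' @param rec an [eeg_recording()].
#' @param spec a [feature_spec()].
#' @return tibble with `channel`, `start_s`, and a list-column `samples` of
#'   numeric windows; zero rows (with a warning) if the recording is shorter
#'   than one window.
#' @export
epochize <- function(rec, spec = feature_spec()) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$sample_rate
  wlen <- round(spec$window_s * fs)
  hop <- spec$hop_s * fs
  dur <- recording_duration(rec)
  empty <- tibble(channel = character(0), start_s = numeric(0),
                  samples = list())
  if (dur < spec$window_s - 1e-9) {
    warn("recording shorter than one epoch window; no epochs produced.")
    return(empty)
  }
  n_ep <- floor((dur - spec$window_s) / spec$hop_s + 1e-9) + 1
  starts <- (seq_len(n_ep) - 1) * spec$hop_s
  ok <- vapply(starts, function(s0) {
    !any(rec$cuts > s0 + 1e-9 & rec$cuts < s0 + spec$window_s - 1e-9)
  }, TRUE)
  starts <- starts[ok]
  tidyr::expand_grid(channel = rec$channels, start_s = starts) |>
    dplyr::mutate(samples = purrr::map2(.data$channel, .data$start_s, function(ch, s0) {
      i0 <- round(s0 * fs)
      rec$signal[match(ch, rec$channels), (i0 + 1):(i0 + wlen)]
    }))
}

#' Label one epoch against suppression intervals
#'
#' The epoch `[start_s, start_s + window_s)` is labelled 1 when its overlap
#' with the union of the intervals is at least
#' `label_overlap_fraction * window_s`.
#'
#' @param start_s epoch start (seconds).
#' @param window_s epoch length (seconds).
#' @param pges_intervals tibble/data frame with `start_s`, `end_s` columns.
#' @param label_overlap_fraction required overlap fraction.
#' @return integer 0 or 1.
#' @export
label_epoch <- function(start_s, window_s, pges_intervals,
                        label_overlap_fraction = 0.5) {
  if (is.null(pges_intervals) || nrow(pges_intervals) == 0) return(0L)
  m <- merge_intervals(pges_intervals$start_s, pges_intervals$end_s)
  ov <- interval_overlap(start_s, start_s + window_s, m$start, m$end)
  as.integer(ov >= label_overlap_fraction * window_s - 1e-9)
}

#' Rectified time-domain statistics of a sample window
#'
#' Mean, standard deviation (sample sd), median, maximum and minimum of the
#' absolute sample values, in that order.
#'
#' @param x numeric sample window (microvolts).
#' @return named numeric vector of 5 statistics.
#' @export
time_features <- function(x) {
  if (length(x) == 0) abort("empty sample window.")
  a <- abs(x)
  c(abs_mean = mean(a), abs_sd = stats::sd(a), abs_median = stats::median(a),
    abs_max = max(a), abs_min = min(a))
}

# Welch power spectral density: Hann-windowed segments with 50% overlap,
# one-sided density in uV^2/Hz.
welch_psd <- function(x, fs, seg_s = 1) {
  n <- length(x)
  seg <- min(n, max(8, round(seg_s * fs)))
  hop <- max(1, floor(seg / 2))
  starts <- seq(1, n - seg + 1, by = hop)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(seg) / (seg + 1)) # Hann
  u <- sum(w^2)
  nf <- floor(seg / 2) + 1
  acc <- numeric(nf)
  for (s0 in starts) {
    seg_x <- x[s0:(s0 + seg - 1)]
    X <- stats::fft((seg_x - mean(seg_x)) * w)
    p <- Mod(X[seq_len(nf)])^2 / (fs * u)
    p[2:(nf - 1)] <- 2 * p[2:(nf - 1)]   # one-sided
    acc <- acc + p
  }
  list(freq = (seq_len(nf) - 1) * fs / seg, psd = acc / length(starts))
}

#' Absolute and relative band powers of a sample window
#'
#' PSD is estimated by Welch's method (1 s Hann segments, 50% overlap) and
#' integrated over each band by the trapezoidal rule. Relative powers divide
#' by the sum of the four band powers, so they add to 1 whenever any band
#' power is positive (and are all 0 for an all-zero window).
#'
#' @param x numeric sample window (microvolts).
#' @param rate sampling rate in Hz.
#' @param spec a [feature_spec()].
#' @return named numeric vector: 4 absolute powers (uV^2) then 4 relative
#'   powers, band order as in `spec$bands`.
#' @export
band_powers <- function(x, rate, spec = feature_spec()) {
  top <- max(vapply(spec$bands, max, 1))
  if (rate <= 2 * top) abort("sampling rate must exceed twice the highest band edge.")
  w <- welch_psd(x, rate, spec$welch_seg_s)
  absp <- vapply(spec$bands, function(b) trapz_band(w$freq, w$psd, b[1], b[2]), 1.0)
  tot <- sum(absp)
  relp <- if (tot > 0) absp / tot else absp * 0
  stats::setNames(
    c(absp, relp),
    c(paste0("bp_", names(spec$bands)), paste0("rel_", names(spec$bands)))
  )
}

# trapezoidal integral of psd over [lo, hi], interpolating at the edges
trapz_band <- function(freq, psd, lo, hi) {
  lo <- max(lo, freq[1])
  hi <- min(hi, freq[length(freq)])
  if (hi <= lo) return(0)
  inside <- freq > lo & freq < hi
  f <- c(lo, freq[inside], hi)
  p <- c(stats::approx(freq, psd, lo)$y, psd[inside],
         stats::approx(freq, psd, hi)$y)
  sum(diff(f) * (head(p, -1) + tail(p, -1)) / 2)
}

#' Petrosian fractal dimension of a sample window
#'
#' `PFD = log10(N) / (log10(N) + log10(N / (N + 0.4 Ndelta)))` where `Ndelta`
#' counts sign changes in the first difference. A monotone window gives
#' exactly 1; more irregular signals give larger values. Invariant to
#' positive rescaling of the signal.
#'
#' @param x numeric sample window, length >= 3.
#' @return PFD value (>= 1).
#' @export
petrosian_fd <- function(x) {
  n <- length(x)
  if (n < 3) abort("Petrosian fractal dimension needs at least 3 samples.")
  d <- diff(x)
  s <- sign(d)
  s <- s[s != 0]
  ndelta <- if (length(s) < 2) 0 else sum(diff(s) != 0)
  log10(n) / (log10(n) + log10(n / (n + 0.4 * ndelta)))
}

compute_feature_vector <- function(x, rate, spec) {
  c(time_features(x), band_powers(x, rate, spec), pfd = petrosian_fd(x))
}

#' Build the per-epoch feature table for a recording
#'
#' One row per (channel, epoch): identity columns, epoch start, the 14
#' features in fixed order (5 rectified time statistics, 4 absolute band
#' powers delta/theta/alpha/beta, 4 relative band powers, PFD) and the
#' suppression label derived from the recording's `pges` annotations.
#'
#' @param rec an [eeg_recording()] (preprocessed; seizures excised).
#' @param spec a [feature_spec()].
#' @return tibble with columns `patient_id`, `session_id`, `channel`,
#'   `start_s`, the 14 feature columns, and `label`.
#' @export
build_feature_table <- function(rec, spec = feature_spec()) {
  stopifnot(inherits(rec, "eeg_recording"))
  eps <- epochize(rec, spec)
  pges <- rec$annotations[rec$annotations$label == "pges", ]
  if (nrow(eps) == 0) {
    out <- tibble(patient_id = character(0), session_id = character(0),
                  channel = character(0), start_s = numeric(0))
    for (nm in feature_names(spec)) out[[nm]] <- numeric(0)
    out$label <- integer(0)
    return(out)
  }
  feats <- purrr::map(eps$samples, compute_feature_vector,
                      rate = rec$sample_rate, spec = spec)
  fmat <- do.call(rbind, feats)
  colnames(fmat) <- feature_names(spec)
  dplyr::bind_cols(
    tibble(patient_id = rec$patient_id, session_id = rec$session_id,
           channel = eps$channel, start_s = eps$start_s),
    as_tibble(fmat),
    tibble(label = vapply(eps$start_s, label_epoch, 0L,
                          window_s = spec$window_s, pges_intervals = pges,
                          label_overlap_fraction = spec$label_overlap_fraction))
  )
}

#' Fit and apply min-max feature scaling
#'
#' `fit_minmax()` learns per-feature minima and maxima on training rows only;
#' `apply_minmax()` maps each feature to `(x - min) / (max - min)`, clipping
#' to `[0, 1]` so out-of-range test values stay in the valid domain of the
#' binary-cross-entropy reconstruction loss. A feature constant in training
#' maps to 0 everywhere.
#'
#' @param data feature tibble (as from [build_feature_table()]).
#' @param feature_cols names of the feature columns.
#' @return `fit_minmax()`: a `minmax_scaler`; `apply_minmax()`: `data` with
#'   scaled feature columns.
#' @export
fit_minmax <- function(data, feature_cols = feature_names()) {
  if (nrow(data) == 0) abort("cannot fit a scaler on zero rows.")
  m <- as.matrix(data[, feature_cols])
  structure(
    list(feature_cols = feature_cols,
         min = apply(m, 2, min), max = apply(m, 2, max)),
    class = "minmax_scaler"
  )
}

#' @rdname fit_minmax
#' @param scaler a fitted `minmax_scaler`.
#' @export
apply_minmax <- function(data, scaler) {
  stopifnot(inherits(scaler, "minmax_scaler"))
  rng <- scaler$max - scaler$min
  for (j in seq_along(scaler$feature_cols)) {
    nm <- scaler$feature_cols[j]
    v <- if (rng[j] > 0) (data[[nm]] - scaler$min[j]) / rng[j] else rep(0, nrow(data))
    data[[nm]] <- pmin(pmax(v, 0), 1)
  }
  data
}
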