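# Preprocessing chain: resample to the device rate, zero-phase Butterworth
# band-pass, 50 Hz notch.
#
# The band-pass is realised as a cascade of second-order sections (biquads)
# computed from the analog Butterworth prototype via the band-pass transform
# and the bilinear transform. At 207 Hz with a 0.5 Hz lower edge the single
# 16-pole transfer-function form is numerically singular in double
# precision, so sections are mandatory, as in any production filtering code.

#' Preprocessing configuration
#'
#' Defaults follow the two-channel subcutaneous-device pipeline: 207 Hz
#' operating rate, 0.5-45 Hz pass-band from an 8th-order Butterworth design,
#' and a 50 Hz mains notch.
#'
#' @param target_rate target sampling rate in Hz.
#' @param low_hz,high_hz band-pass edges in Hz.
#' @param butter_order Butterworth design order (even, >= 2); the digital
#'   band-pass has twice this many poles, before zero-phase doubling.
#' @param notch_hz notch centre frequency in Hz.
#' @param notch_q notch quality factor; 30 gives about 1.7 Hz of -3 dB
#'   bandwidth at 50 Hz, leaving frequencies more than 5 Hz away within 1 dB.
#' @return a `preprocess_config` list.
#' @export
preprocess_config <- function(target_rate = 207, low_hz = 0.5, high_hz = 45,
                              butter_order = 8, notch_hz = 50, notch_q = 30) {
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < target_rate / 2)) {
    abort("need 0 < low_hz < high_hz < target_rate / 2.")
  }
  if (butter_order < 2 || butter_order %% 2 != 0) {
    abort("butter_order must be an even integer >= 2.")
  }
  structure(
    list(target_rate = target_rate, low_hz = low_hz, high_hz = high_hz,
         butter_order = butter_order, notch_hz = notch_hz, notch_q = notch_q),
    class = "preprocess_config"
  )
}

# ---- second-order-section Butterworth band-pass -----------------------------

# Digital Butterworth band-pass of prototype order n as a list of biquads.
# Analog prototype poles -> lp2bp transform -> bilinear transform; conjugate
# pole pairs become sections, each given one zero at z = 1 and one at z = -1.
butter_bandpass_sos <- function(n, low_hz, high_hz, fs) {
  fs2 <- 2 * fs
  w1 <- fs2 * tan(pi * low_hz / fs)   # pre-warped edge frequencies
  w2 <- fs2 * tan(pi * high_hz / fs)
  w0 <- sqrt(w1 * w2)
  bw <- w2 - w1

  k <- seq_len(n)
  proto <- exp(1i * pi * (2 * k + n - 1) / (2 * n))   # left-half-plane poles

  half <- bw * proto / 2
  s_poles <- c(half + sqrt(half^2 - w0^2), half - sqrt(half^2 - w0^2))

  z_poles <- (fs2 + s_poles) / (fs2 - s_poles)
  # n zeros at s = 0 -> z = 1; degree deficit gives n zeros at z = -1
  gain <- bw^n * Re(fs2^n / prod(fs2 - s_poles))

  # pair conjugate poles: take one of each conjugate pair
  pp <- z_poles[Im(z_poles) >= 0]
  pp <- pp[order(-abs(pp))]           # closest to unit circle first
  sos <- lapply(pp, function(p) {
    a <- c(1, -2 * Re(p), abs(p)^2)
    list(b = c(1, 0, -1), a = a)      # zeros at +1 and -1
  })
  # distribute the overall gain across sections to keep intermediates tame
  g_per <- abs(Re(gain))^(1 / length(sos))
  sos <- lapply(sos, function(s) { s$b <- s$b * g_per; s })
  sos
}

# Filter one biquad starting from the steady state for a constant input
# equal to the first sample, so step-like signals produce no start transient.
biquad_steady <- function(s, x) {
  h1 <- sum(s$b) / sum(s$a)
  as.numeric(signal::filter(s$b, s$a, x,
                            init.x = rep(x[1], 2), init.y = rep(h1 * x[1], 2)))
}

# One forward-backward (zero-phase) pass of a biquad cascade with reflective
# edge padding to suppress end transients.
filtfilt_sos <- function(sos, x) {
  n <- length(x)
  pad <- max(4, min(n - 1, 99))
  xp <- c(2 * x[1] - rev(x[2:(pad + 1)]), x, 2 * x[n] - rev(x[(n - pad):(n - 1)]))
  y <- xp
  for (s in sos) y <- biquad_steady(s, y)
  y <- rev(y)
  for (s in sos) y <- biquad_steady(s, y)
  rev(y)[(pad + 1):(pad + n)]
}

apply_channelwise <- function(rec, f) {
  sig <- t(apply(rec$signal, 1, f))
  if (ncol(rec$signal) == 1) sig <- matrix(sig, nrow = nrow(rec$signal))
  eeg_recording(sig, rec$sample_rate, rec$channels,
                patient_id = rec$patient_id, session_id = rec$session_id,
                annotations = rec$annotations, cuts = rec$cuts)
}

#' Resample a recording
#'
#' Anti-aliased polyphase resampling to `target_rate` (downsampling only;
#' annotation times are in seconds and unchanged).
#'
#' @param rec an [eeg_recording()].
#' @param target_rate new rate in Hz.
#' @return resampled [eeg_recording()].
#' @export
resample_recording <- function(rec, target_rate) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (target_rate > rec$sample_rate + 1e-9) {
    abort("upsampling is not supported; target_rate must not exceed the current rate.")
  }
  if (abs(target_rate - rec$sample_rate) < 1e-9) return(rec)
  ratio <- target_rate / rec$sample_rate
  m <- round(ncol(rec$signal) * ratio)
  sig <- t(apply(rec$signal, 1, function(x) resample_fft(x, m)))
  if (nrow(rec$signal) == 1) sig <- matrix(sig, nrow = 1)
  eeg_recording(sig, target_rate, rec$channels,
                patient_id = rec$patient_id, session_id = rec$session_id,
                annotations = rec$annotations, cuts = rec$cuts)
}

# Fourier-domain resampling of x to m samples: truncate the spectrum at the
# new Nyquist frequency (an ideal anti-aliasing low-pass for band-limited
# signals). The line through the endpoints is removed first and restored
# after, so non-periodic signals do not ring at the wrap-around.
resample_fft <- function(x, m) {
  n <- length(x)
  trend <- x[1] + (x[n] - x[1]) * (seq_len(n) - 1) / max(1, n - 1)
  X <- stats::fft(x - trend)
  Y <- complex(m)
  nh <- min(n, m)
  keep <- floor((nh - 1) / 2)           # positive-frequency bins kept
  Y[1] <- X[1]
  if (keep > 0) {
    Y[2:(keep + 1)] <- X[2:(keep + 1)]
    Y[(m - keep + 1):m] <- X[(n - keep + 1):n]
  }
  if (nh %% 2 == 0 && nh < n) {
    # shared Nyquist bin, split to keep the signal real
    Y[keep + 2] <- X[keep + 2] / 2
    Y[m - keep] <- Y[m - keep] + Conj(X[keep + 2]) / 2
  }
  y <- Re(stats::fft(Y, inverse = TRUE)) / n
  new_trend <- trend[1] + (trend[n] - trend[1]) * (seq_len(m) - 1) / max(1, m - 1)
  y + new_trend
}

#' Band-pass filter a recording
#'
#' Zero-phase (forward-backward) Butterworth band-pass applied per channel;
#' output length equals input length.
#'
#' @param rec an [eeg_recording()].
#' @param cfg a [preprocess_config()].
#' @return filtered [eeg_recording()].
#' @export
bandpass_recording <- function(rec, cfg = preprocess_config()) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (rec$sample_rate <= 2 * cfg$high_hz) {
    abort("sample rate must exceed twice the upper band edge.")
  }
  sos <- butter_bandpass_sos(cfg$butter_order, cfg$low_hz, cfg$high_hz,
                             rec$sample_rate)
  apply_channelwise(rec, function(x) filtfilt_sos(sos, x))
}

# RBJ cookbook notch biquad
notch_biquad <- function(f0, fs, q) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

#' Notch filter a recording
#'
#' Zero-phase second-order IIR notch (default 50 Hz, Q = 30) to remove mains
#' interference left after band-pass roll-off.
#'
#' @inheritParams bandpass_recording
#' @return filtered [eeg_recording()].
#' @export
notch_recording <- function(rec, cfg = preprocess_config()) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (cfg$notch_hz >= rec$sample_rate / 2) {
    abort("notch frequency must be below the Nyquist frequency.")
  }
  bi <- notch_biquad(cfg$notch_hz, rec$sample_rate, cfg$notch_q)
  apply_channelwise(rec, function(x) filtfilt_sos(list(bi), x))
}

#' Run the full preprocessing chain
#'
#' Resample to `cfg$target_rate` (when needed), band-pass, then notch — the
#' order used for device-rate harmonisation of scalp recordings.
#'
#' @inheritParams bandpass_recording
#' @return preprocessed [eeg_recording()].
#' @export
preprocess_recording <- function(rec, cfg = preprocess_config()) {
  rec |>
    resample_recording(cfg$target_rate) |>
    bandpass_recording(cfg) |>
    notch_recording(cfg)
}
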