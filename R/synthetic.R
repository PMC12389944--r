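# Synthetic annotated two-channel EEG cohorts.
#
# Each session is: background, an annotated seizure segment (content
# irrelevant — it is excised before analysis), a suppression (PGES) interval
# starting within 30 s of seizure end, then background. Background is
# band-limited 1/f-shaped noise with an optional 10 Hz alpha rhythm; the
# suppression segment is the same process scaled to a few microvolts with
# raised-cosine tapers at its edges. The two channels share a common
# component so they correlate like neighbouring electrodes.

#' Synthetic cohort configuration
#'
#' Defaults emulate the clinical material the detector targets: 207 Hz
#' two-channel recordings, background activity of tens of microvolts,
#' suppression amplitude well under 10 uV, suppression durations
#' N(27.1, 2.6^2) s (truncated at 1 s), patients split 10/7/9 into
#' train/validation/test, and a background-heavy training composition.
#'
#' @param n_patients number of patients (default 26).
#' @param sessions_per_patient sessions per patient (default 2).
#' @param sample_rate Hz (default 207).
#' @param background_rms_uv background RMS amplitude in uV (default 35).
#' @param suppression_rms_uv suppression RMS amplitude in uV (default 2,
#'   keeping peak amplitude under the 10 uV criterion).
#' @param pges_duration_mean_s,pges_duration_sd_s suppression-duration
#'   distribution (default 27.1 and 2.6 s).
#' @param seizure_duration_s annotated seizure length (default 20 s).
#' @param pre_s,post_s background padding before the seizure and after the
#'   suppression window (defaults 40 and 60 s).
#' @param channel_correlation weight of the component shared by the two
#'   channels, in `[0, 1)` (default 0.6).
#' @param alpha_rhythm_fraction amplitude fraction of a 10 Hz rhythm added to
#'   the background (default 0.3).
#' @param patient_scale_sd lognormal sd of the per-patient amplitude factor
#'   (default 0.15).
#' @param background_to_pges_ratio target ratio of background to suppression
#'   epochs in the training split, achieved by generating suppression-free
#'   training sessions (default 20).
#' @param split_sizes named integer vector, patients per split
#'   (default `c(train = 10, val = 7, test = 9)`).
#' @param seed master seed.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_patients = 26, sessions_per_patient = 2,
                             sample_rate = 207,
                             background_rms_uv = 35, suppression_rms_uv = 2,
                             pges_duration_mean_s = 27.1,
                             pges_duration_sd_s = 2.6,
                             seizure_duration_s = 20,
                             pre_s = 40, post_s = 60,
                             channel_correlation = 0.6,
                             alpha_rhythm_fraction = 0.3,
                             patient_scale_sd = 0.15,
                             background_to_pges_ratio = 20,
                             split_sizes = c(train = 10, val = 7, test = 9),
                             seed = 42) {
  # equality is allowed: a zero-contrast cohort is the negative control
  if (suppression_rms_uv > background_rms_uv) {
    abort("suppression_rms_uv must not exceed background_rms_uv.")
  }
  stopifnot(pges_duration_mean_s > 0, seizure_duration_s > 0,
            pre_s > 0, post_s > 0,
            channel_correlation >= 0, channel_correlation < 1,
            alpha_rhythm_fraction >= 0, alpha_rhythm_fraction <= 1)
  if (n_patients < sum(split_sizes)) {
    abort("n_patients must cover the train/val/test split sizes.")
  }
  structure(as.list(environment()), class = "synthetic_config")
}

# band-limited 1/f-shaped noise, unit RMS, via spectral shaping
one_over_f_noise <- function(n, fs, low = 0.5, high = 45, exponent = 1) {
  X <- stats::fft(rnorm(n))
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)                          # two-sided frequency axis
  amp <- ifelse(f >= low & f <= high, 1 / pmax(f, low)^(exponent / 2), 0)
  x <- Re(stats::fft(X * amp, inverse = TRUE)) / n
  x / stats::sd(x)
}

# raised-cosine amplitude envelope dropping to `depth` inside [a, b) with
# taper_s-long cosine edges
suppression_envelope <- function(n, fs, a, b, depth, taper_s = 1) {
  t <- (seq_len(n) - 1) / fs
  env <- rep(1, n)
  tp <- taper_s
  inside <- t >= a & t < b
  env[inside] <- depth
  fall <- t >= a - tp & t < a
  env[fall] <- depth + (1 - depth) * (1 + cos(pi * (t[fall] - (a - tp)) / tp)) / 2
  rise <- t >= b & t < b + tp
  env[rise] <- depth + (1 - depth) * (1 - cos(pi * (t[rise] - b) / tp)) / 2
  env
}

rtruncnorm1 <- function(mean, sd, lower) {
  repeat {
    x <- rnorm(1, mean, sd)
    if (x >= lower) return(x)
  }
}

#' Generate one synthetic annotated session
#'
#' Timeline: `pre_s` background, an annotated seizure of
#' `seizure_duration_s`, suppression starting uniformly within 30 s of
#' seizure end with duration drawn from the configured truncated normal,
#' then background padding. Both the seizure and the suppression interval are
#' annotated; seizure content is arbitrary high-amplitude noise because it is
#' excised before analysis.
#'
#' @param cfg a [synthetic_config()].
#' @param patient_id,session_id identity strings.
#' @param patient_factor per-patient amplitude multiplier.
#' @param seed seed for this session.
#' @param with_pges set `FALSE` for a background-only session (no
#'   suppression annotation, no suppression in the signal).
#' @return an [eeg_recording()] with two channels `FP2-F8`, `T8-F8`.
#' @export
generate_session <- function(cfg = synthetic_config(), patient_id = "SP01",
                             session_id = "S01", patient_factor = 1,
                             seed = 1, with_pges = TRUE) {
  set.seed(seed)
  fs <- cfg$sample_rate

  pges_dur <- if (with_pges) {
    rtruncnorm1(cfg$pges_duration_mean_s, cfg$pges_duration_sd_s, lower = 1)
  } else 0
  pges_gap <- if (with_pges) runif(1, 0, 30) else 0

  seiz_start <- cfg$pre_s
  seiz_end <- seiz_start + cfg$seizure_duration_s
  pges_start <- seiz_end + pges_gap
  pges_end <- pges_start + pges_dur
  total_s <- ceiling(pges_end + cfg$post_s)
  n <- round(total_s * fs)

  mk_channel <- function(shared) {
    own <- one_over_f_noise(n, fs)
    x <- sqrt(cfg$channel_correlation) * shared +
      sqrt(1 - cfg$channel_correlation) * own
    if (cfg$alpha_rhythm_fraction > 0) {
      ph <- runif(1, 0, 2 * pi)
      x <- x + cfg$alpha_rhythm_fraction *
        sin(2 * pi * 10 * (seq_len(n) - 1) / fs + ph)
      x <- x / stats::sd(x)
    }
    x
  }
  shared <- one_over_f_noise(n, fs)
  sig <- rbind(mk_channel(shared), mk_channel(shared)) *
    cfg$background_rms_uv * patient_factor

  if (with_pges) {
    depth <- cfg$suppression_rms_uv / cfg$background_rms_uv
    env <- suppression_envelope(n, fs, pges_start, pges_end, depth)
    sig <- sweep(sig, 2, env, "*")
  }

  # seizure content: high-amplitude noise, excised before analysis anyway
  si <- (round(seiz_start * fs) + 1):(round(seiz_end * fs))
  sig[, si] <- sig[, si] + matrix(rnorm(2 * length(si)), 2) *
    3 * cfg$background_rms_uv * patient_factor

  ann <- tibble(start_s = seiz_start, end_s = seiz_end, label = "seizure")
  if (with_pges) {
    ann <- dplyr::bind_rows(
      ann, tibble(start_s = pges_start, end_s = pges_end, label = "pges")
    )
  }
  eeg_recording(sig, fs, c("FP2-F8", "T8-F8"),
                patient_id = patient_id, session_id = session_id,
                annotations = ann)
}

#' Generate a synthetic annotated cohort
#'
#' Draws per-patient amplitude factors lognormally, generates
#' `sessions_per_patient` sessions per patient, and assigns patients to
#' disjoint train/validation/test splits. To honour the background-heavy
#' training composition of anomaly detection, suppression is included in
#' only a fraction of training sessions (roughly one suppression epoch per
#' `background_to_pges_ratio` background epochs); validation and test
#' sessions always contain suppression so calibration and evaluation have
#' both classes.
#'
#' @param cfg a [synthetic_config()].
#' @return a `synthetic_cohort`: list with `recordings` (list of
#'   [eeg_recording()]), `split` (named list of patient-id vectors), and
#'   `manifest` tibble (`patient_id`, `session_id`, `split`, `has_pges`).
#' @export
generate_cohort <- function(cfg = synthetic_config()) {
  set.seed(derive_seed(cfg$seed, "cohort"))
  pats <- sprintf("SP%02d", seq_len(cfg$n_patients))
  factors <- stats::setNames(exp(rnorm(cfg$n_patients, 0, cfg$patient_scale_sd)), pats)

  ss <- cfg$split_sizes
  split <- list(
    train = pats[seq_len(ss["train"])],
    val = pats[ss["train"] + seq_len(ss["val"])],
    test = pats[ss["train"] + ss["val"] + seq_len(ss["test"])]
  )
  leftover <- setdiff(pats, unlist(split))
  if (length(leftover) > 0) split$train <- c(split$train, leftover)

  # fraction of training sessions carrying suppression so that suppression
  # epochs ~ background epochs / ratio (a suppression interval occupies
  # roughly a tenth of a session's epochs)
  sess_frac <- min(1, 10 / cfg$background_to_pges_ratio)

  manifest <- list()
  recordings <- list()
  k <- 0
  for (p in pats) {
    sp <- names(which(vapply(split, function(s) p %in% s, TRUE)))[1]
    for (s in seq_len(cfg$sessions_per_patient)) {
      k <- k + 1
      sid <- sprintf("S%02d", s)
      sseed <- derive_seed(cfg$seed, paste0(p, "_", sid))
      with_pges <- if (sp == "train") {
        set.seed(derive_seed(sseed, "haspges"))
        runif(1) < sess_frac
      } else TRUE
      recordings[[k]] <- generate_session(
        cfg, patient_id = p, session_id = sid,
        patient_factor = factors[[p]], seed = sseed, with_pges = with_pges
      )
      manifest[[k]] <- tibble(patient_id = p, session_id = sid,
                              split = sp, has_pges = with_pges)
    }
  }
  structure(
    list(recordings = recordings, split = split,
         manifest = dplyr::bind_rows(manifest), config = cfg),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "<synthetic_cohort> %d patients (%d/%d/%d train/val/test), %d sessions\n",
    x$config$n_patients, length(x$split$train), length(x$split$val),
    length(x$split$test), length(x$recordings)
  ))
  invisible(x)
}

#' Write a cohort to disk
#'
#' One recording file per session (EDF or tabular by `format`), annotation
#' sidecars, and a JSON manifest listing patients, sessions and split
#' membership.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @param format `"tabular"` or `"edf"`.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, format = c("tabular", "edf")) {
  format <- match.arg(format)
  ext <- if (format == "edf") "edf" else "csv"
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (rec in cohort$recordings) {
    write_recording(rec, file.path(dir, sprintf("%s_%s.%s", rec$patient_id,
                                                rec$session_id, ext)))
  }
  jsonlite::write_json(
    list(split = cohort$split, manifest = cohort$manifest),
    file.path(dir, "manifest.json")
  )
  invisible(dir)
}
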