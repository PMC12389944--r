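# Shared fixtures and independent oracles.

# small deterministic recording: named channels, optional annotations
make_recording <- function(n_channels = 2, duration_s = 20, fs = 100,
                           channels = NULL, annotations = NULL, seed = 1) {
  set.seed(seed)
  n <- round(duration_s * fs)
  channels <- channels %||% paste0("CH", seq_len(n_channels))
  sig <- matrix(rnorm(n_channels * n, sd = 30), n_channels, n)
  eeg_recording(sig, fs, channels,
                patient_id = "P01", session_id = "S01",
                annotations = annotations %||% pgesr::empty_annotations())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

ann_tbl <- function(...) {
  rows <- list(...)
  dplyr::bind_rows(lapply(rows, function(r) {
    tibble::tibble(start_s = r[[1]], end_s = r[[2]], label = r[[3]])
  }))
}

# Independent brute-force re-implementation of the majority-flip smoother:
# same convention (window W epochs, step 1, sequential in place, symmetric
# boundary test, strict majority, ties unchanged, final window skipped) but
# written with explicit counting rather than vector arithmetic.
flip_oracle <- function(p, w = 4L) {
  p <- as.integer(p)
  n <- length(p)
  if (n <= w) return(p)
  i <- 1L
  while (i + w <= n) {
    last_in <- p[i + w - 1L]
    first_out <- p[i + w]
    if (last_in != first_out) {
      n1 <- 0L
      for (j in i:(i + w - 1L)) n1 <- n1 + (p[j] == 1L)
      n0 <- w - n1
      if (n1 > n0) {
        for (j in i:(i + w - 1L)) p[j] <- 1L
      } else if (n0 > n1) {
        for (j in i:(i + w - 1L)) p[j] <- 0L
      }
    }
    i <- i + 1L
  }
  p
}

# direct-count classification metrics oracle
metrics_oracle <- function(y_true, y_pred, positive = 1) {
  tp <- sum(y_true == positive & y_pred == positive)
  fp <- sum(y_true != positive & y_pred == positive)
  fn <- sum(y_true == positive & y_pred != positive)
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  c(precision = prec, recall = rec, f1 = f1)
}

# brute-force best F1 over every candidate cut (checks select_threshold):
# evaluates F1 at all midpoints AND at every observed score value
best_f1_oracle <- function(bg, pg) {
  cand <- sort(unique(c(bg, pg)))
  cand <- c(cand - 1e-12, cand, (head(cand, -1) + tail(cand, -1)) / 2,
            min(cand) - 1)
  f1s <- vapply(cand, function(th) {
    tp <- sum(pg > th); fp <- sum(bg > th)
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- tp / length(pg)
    if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  }, 1.0)
  max(f1s)
}

# small featurised cohort, cached per test run
small_cohort_config <- function(seed = 11) {
  synthetic_config(
    n_patients = 6, sessions_per_patient = 1,
    pre_s = 20, post_s = 30, seizure_duration_s = 10,
    split_sizes = c(train = 2, val = 2, test = 2), seed = seed
  )
}
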