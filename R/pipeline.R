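# End-to-end orchestration: cohort -> features -> scaled matrix -> VAE ->
# calibrated threshold -> smoothed predictions -> durations and metrics.

#' Featurise every recording of a cohort
#'
#' For each recording: excise annotated seizure segments, run the
#' preprocessing chain (resample / band-pass / notch), and extract the
#' per-epoch feature table. Epochs never span a seizure splice.
#'
#' @param cohort a `synthetic_cohort`, or a plain list of [eeg_recording()]s.
#' @param pre_cfg a [preprocess_config()].
#' @param spec a [feature_spec()].
#' @return tibble of epoch rows for all recordings (see
#'   [build_feature_table()]), with a `split` column when the cohort carries
#'   a split.
#' @export
featurize_cohort <- function(cohort, pre_cfg = preprocess_config(),
                             spec = feature_spec()) {
  recs <- if (inherits(cohort, "synthetic_cohort")) cohort$recordings else cohort
  rows <- purrr::map_dfr(recs, function(rec) {
    rec |>
      excise_intervals("seizure") |>
      preprocess_recording(pre_cfg) |>
      build_feature_table(spec)
  })
  if (inherits(cohort, "synthetic_cohort")) {
    split_tbl <- purrr::imap_dfr(cohort$split, function(p, nm) {
      tibble(patient_id = p, split = nm)
    })
    rows <- dplyr::left_join(rows, split_tbl, by = "patient_id")
  }
  rows
}

#' True per-session suppression durations
#'
#' Sums the annotated `pges` interval lengths of each recording (0 for
#' background-only sessions).
#'
#' @param cohort a `synthetic_cohort` or list of [eeg_recording()]s.
#' @return tibble with `patient_id`, `session_id`, `true_duration_s`.
#' @export
true_session_durations <- function(cohort) {
  recs <- if (inherits(cohort, "synthetic_cohort")) cohort$recordings else cohort
  purrr::map_dfr(recs, function(rec) {
    pg <- rec$annotations[rec$annotations$label == "pges", ]
    tibble(patient_id = rec$patient_id, session_id = rec$session_id,
           true_duration_s = sum(pg$end_s - pg$start_s))
  })
}

#' Fit the suppression detector
#'
#' Learns the min-max scaler on the training split only, trains the VAE on
#' the scaled training rows, scores the validation rows, and calibrates the
#' anomaly threshold by F1 scan on the validation labels. The result bundles
#' everything needed to score new recordings.
#'
#' @param features epoch-row tibble from [featurize_cohort()] with a `split`
#'   column (or pass `split` explicitly as a named list of patient ids).
#' @param vae_cfg a [vae_config()].
#' @param split optional named list with `train` and `val` patient-id
#'   vectors, used when `features` lacks a `split` column.
#' @param feature_cols feature column names.
#' @return a `pges_model`: list with `fit` (`pges_vae`), `scaler`,
#'   `threshold`, `calibration` (F1/precision/recall at the threshold) and
#'   `feature_cols`.
#' @export
pges_fit <- function(features, vae_cfg = vae_config(), split = NULL,
                     feature_cols = feature_names()) {
  if (!is.null(split)) {
    features$split <- dplyr::case_when(
      features$patient_id %in% split$train ~ "train",
      features$patient_id %in% split$val ~ "val",
      TRUE ~ "test"
    )
  }
  if (!"split" %in% names(features)) {
    abort("features need a 'split' column (or pass `split`).")
  }
  tr <- features[features$split == "train", ]
  va <- features[features$split == "val", ]
  if (nrow(tr) == 0) abort("empty training split.")
  if (!any(va$label == 1) || !any(va$label == 0)) {
    abort("threshold calibration needs both background and suppression rows in the validation split.")
  }

  scaler <- fit_minmax(tr, feature_cols)
  tr_s <- apply_minmax(tr, scaler)
  va_s <- apply_minmax(va, scaler)

  fit <- vae_train(tr_s, va_s, vae_cfg, feature_cols)
  scores <- anomaly_score(fit, va_s)
  cal <- select_threshold(scores[va_s$label == 0], scores[va_s$label == 1])

  structure(
    list(fit = fit, scaler = scaler, threshold = cal$threshold,
         calibration = cal, feature_cols = feature_cols),
    class = "pges_model"
  )
}

#' @export
print.pges_model <- function(x, ...) {
  cat(sprintf(
    "<pges_model> threshold %.4g (validation F1 %.3f); ",
    x$threshold, x$calibration$f1
  ))
  print(x$fit)
  invisible(x)
}

#' One-row summary of a fitted detector
#' @param x a `pges_model`.
#' @param ... unused.
#' @return tibble combining VAE summary with the calibrated threshold.
#' @export
glance.pges_model <- function(x, ...) {
  dplyr::bind_cols(
    glance(x$fit),
    tibble(threshold = x$threshold, val_f1 = x$calibration$f1)
  )
}

#' Score and classify epoch rows
#'
#' Applies the model's scaler, computes deterministic anomaly scores, and
#' thresholds them into 0/1 suppression predictions.
#'
#' @param model a `pges_model`.
#' @param features epoch-row tibble (unscaled).
#' @return `features` with `score` and `pred` columns appended.
#' @export
pges_predict <- function(model, features) {
  stopifnot(inherits(model, "pges_model"))
  scaled <- apply_minmax(features, model$scaler)
  features$score <- anomaly_score(model$fit, scaled)
  features$pred <- classify(features$score, model$threshold)
  features
}

#' Smooth predictions and estimate per-patient durations
#'
#' Orders each (patient, session, channel) prediction sequence by epoch
#' start, applies the majority-flip smoother, takes the longest positive run
#' as the session/channel duration, and averages per patient against the
#' annotated truth.
#'
#' @param predictions tibble from [pges_predict()] (needs `patient_id`,
#'   `session_id`, `channel`, `start_s`, `pred`).
#' @param true_durations tibble from [true_session_durations()].
#' @param window_s smoothing window (seconds, default 10).
#' @param hop_s epoch hop (seconds, default 2.5).
#' @return list with `smoothed` (predictions with `pred_smooth`),
#'   `sequence_durations` (per session x channel) and `report` (per patient,
#'   from [patient_duration()]).
#' @export
predict_durations <- function(predictions, true_durations,
                              window_s = 10, hop_s = 2.5) {
  smoothed <- predictions |>
    dplyr::group_by(.data$patient_id, .data$session_id, .data$channel) |>
    dplyr::arrange(.data$start_s, .by_group = TRUE) |>
    dplyr::mutate(pred_smooth = flip_misclassified(.data$pred, window_s, hop_s)) |>
    dplyr::ungroup()

  seq_dur <- smoothed |>
    dplyr::group_by(.data$patient_id, .data$session_id, .data$channel) |>
    dplyr::summarise(
      predicted_duration_s = longest_run_duration(.data$pred_smooth, hop_s),
      .groups = "drop"
    ) |>
    dplyr::left_join(true_durations, by = c("patient_id", "session_id"))

  list(smoothed = smoothed, sequence_durations = seq_dur,
       report = patient_duration(seq_dur))
}

#' Run the complete synthetic experiment
#'
#' Generates (or accepts) a cohort, featurises it, fits the detector on the
#' train/validation splits, and evaluates the test split: epoch-level
#' metrics, event-level detection rate, and the per-patient duration-offset
#' table.
#'
#' @param cohort a `synthetic_cohort` (or `NULL` to generate one from `syn_cfg`).
#' @param syn_cfg a [synthetic_config()] used when `cohort` is `NULL`.
#' @param pre_cfg a [preprocess_config()].
#' @param spec a [feature_spec()].
#' @param vae_cfg a [vae_config()].
#' @param smooth_window_s majority-flip window (seconds).
#' @return list with `model`, `features`, `test_predictions`, `metrics`
#'   (epoch-level, pre-smoothing), `detection_rate`, `durations` (per-patient
#'   report), `average_offset_s`.
#' @export
run_pges_experiment <- function(cohort = NULL, syn_cfg = synthetic_config(),
                                pre_cfg = preprocess_config(),
                                spec = feature_spec(),
                                vae_cfg = vae_config(),
                                smooth_window_s = 10) {
  if (is.null(cohort)) cohort <- generate_cohort(syn_cfg)
  features <- featurize_cohort(cohort, pre_cfg, spec)
  model <- pges_fit(features, vae_cfg)

  test <- features[features$split == "test", ]
  preds <- pges_predict(model, test)
  metrics <- classification_metrics(preds$label, preds$pred)

  true_dur <- true_session_durations(cohort)
  test_sessions <- unique(preds[, c("patient_id", "session_id")])
  dur <- predict_durations(preds, true_dur, smooth_window_s, spec$hop_s)

  events <- purrr::map_dfr(cohort$recordings, function(rec) {
    pg <- rec$annotations[rec$annotations$label == "pges", ]
    if (nrow(pg) == 0) return(NULL)
    tibble(patient_id = rec$patient_id, session_id = rec$session_id,
           start_s = pg$start_s, end_s = pg$end_s)
  })
  # events are annotated on the original timeline; epochs live on the
  # seizure-excised timeline, so shift by the excised time before each event
  events <- dplyr::left_join(
    events,
    purrr::map_dfr(cohort$recordings, function(rec) {
      sz <- rec$annotations[rec$annotations$label == "seizure", ]
      tibble(patient_id = rec$patient_id, session_id = rec$session_id,
             excised_s = sum(sz$end_s - sz$start_s))
    }),
    by = c("patient_id", "session_id")
  ) |>
    dplyr::mutate(start_s = .data$start_s - .data$excised_s,
                  end_s = .data$end_s - .data$excised_s)

  test_events <- dplyr::semi_join(events, test_sessions,
                                  by = c("patient_id", "session_id"))
  det <- if (nrow(test_events) > 0) {
    event_detection_rate(
      test_events,
      dplyr::rename(dur$smoothed, pred_raw = "pred", pred = "pred_smooth"),
      window_s = spec$window_s
    )
  } else NA_real_

  off <- cohort_offset_table(dur$report)
  list(model = model, features = features, test_predictions = preds,
       metrics = metrics, detection_rate = det,
       durations = off$table, average_offset_s = off$average_offset_s,
       smoothed = dur$smoothed, sequence_durations = dur$sequence_durations)
}

# ---- checkpointing ----------------------------------------------------------

#' Save or load a detector checkpoint
#'
#' The checkpoint is a portable JSON container holding the VAE weights,
#' configuration, loss history, scaler parameters and calibrated threshold.
#'
#' @param model a `pges_model`.
#' @param path JSON file path.
#' @return `save_checkpoint()`: `path`, invisibly; `load_checkpoint()`: a
#'   `pges_model`.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "pges_model"))
  obj <- list(
    config = unclass(model$fit$config),
    par = lapply(model$fit$par, function(p) {
      if (is.matrix(p)) list(dim = dim(p), data = as.numeric(p))
      else list(dim = NULL, data = as.numeric(p))
    }),
    loss_history = model$fit$loss_history,
    scaler = list(feature_cols = model$scaler$feature_cols,
                  min = unname(model$scaler$min), max = unname(model$scaler$max)),
    threshold = model$threshold,
    calibration = model$calibration,
    feature_cols = model$feature_cols
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  par <- lapply(obj$par, function(p) {
    if (length(p$dim) == 2) {
      matrix(as.numeric(p$data), p$dim[[1]], p$dim[[2]])
    } else {
      as.numeric(p$data)
    }
  })
  cfg <- do.call(vae_config, obj$config)
  fit <- structure(
    list(par = par, config = cfg, feature_cols = obj$feature_cols,
         loss_history = as_tibble(obj$loss_history)),
    class = "pges_vae"
  )
  scaler <- structure(
    list(feature_cols = obj$scaler$feature_cols,
         min = stats::setNames(obj$scaler$min, obj$scaler$feature_cols),
         max = stats::setNames(obj$scaler$max, obj$scaler$feature_cols)),
    class = "minmax_scaler"
  )
  structure(
    list(fit = fit, scaler = scaler, threshold = obj$threshold,
         calibration = obj$calibration, feature_cols = obj$feature_cols),
    class = "pges_model"
  )
}

#' Plot validation score distributions with the calibrated threshold
#'
#' @param predictions tibble with `score` and `label` columns (e.g. from
#'   [pges_predict()]).
#' @param threshold optional threshold to mark.
#' @return a ggplot.
#' @export
plot_score_distributions <- function(predictions, threshold = NULL) {
  p <- predictions |>
    dplyr::mutate(class = ifelse(.data$label == 1, "PGES", "background")) |>
    ggplot2::ggplot(ggplot2::aes(.data$score, fill = .data$class)) +
    ggplot2::geom_histogram(alpha = 0.6, position = "identity", bins = 60) +
    ggplot2::labs(x = "anomaly score (mean BCE)", y = "epochs", fill = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_vline(xintercept = threshold, linetype = "dashed")
  }
  p
}
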