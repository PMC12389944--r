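# Classification metrics, event-level detection rate, and the
# learning-curve experiment over training-cohort size.

#' Epoch-level classification metrics
#'
#' Precision, recall and F1 computed twice — once with suppression (label 1)
#' as the positive class and once with background (label 0) — plus the 2x2
#' confusion matrix in raw counts and both row- and column-normalised form,
#' and the false-positive rate FP / (FP + TN) with suppression positive.
#' Zero-denominator metrics are reported as 0 and flagged.
#'
#' @param y_true,y_pred equal-length binary vectors.
#' @return a `pges_metrics` list: `metrics` tibble (per class), `confusion`
#'   (counts), `confusion_row_norm`, `confusion_col_norm`,
#'   `false_positive_rate`, `accuracy`, `degenerate` flag.
#' @export
classification_metrics <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) abort("y_true and y_pred differ in length.")
  if (length(y_true) == 0) abort("empty inputs.")
  y_true <- as.integer(y_true)
  y_pred <- as.integer(y_pred)

  cm <- matrix(0, 2, 2, dimnames = list(true = c("0", "1"), pred = c("0", "1")))
  for (t in 0:1) for (p in 0:1) cm[t + 1, p + 1] <- sum(y_true == t & y_pred == p)

  degenerate <- FALSE
  per_class <- purrr::map_dfr(c(background = 0, pges = 1), function(pos) {
    tp <- sum(y_true == pos & y_pred == pos)
    fp <- sum(y_true != pos & y_pred == pos)
    fn <- sum(y_true == pos & y_pred != pos)
    prec <- if (tp + fp > 0) tp / (tp + fp) else { degenerate <<- TRUE; 0 }
    rec <- if (tp + fn > 0) tp / (tp + fn) else { degenerate <<- TRUE; 0 }
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    tibble(precision = prec, recall = rec, f1 = f1)
  }, .id = "class")

  fp <- cm["0", "1"]; tn <- cm["0", "0"]
  fpr <- if (fp + tn > 0) fp / (fp + tn) else { degenerate <- TRUE; 0 }
  row_n <- sweep(cm, 1, pmax(rowSums(cm), 1), "/")
  col_n <- sweep(cm, 2, pmax(colSums(cm), 1), "/")

  structure(
    list(metrics = per_class, confusion = cm,
         confusion_row_norm = row_n, confusion_col_norm = col_n,
         false_positive_rate = fpr,
         accuracy = sum(diag(cm)) / length(y_true),
         degenerate = degenerate),
    class = "pges_metrics"
  )
}

#' @export
print.pges_metrics <- function(x, ...) {
  cat("<pges_metrics>\n")
  print(x$metrics)
  cat(sprintf("false positive rate: %.3f  accuracy: %.3f\n",
              x$false_positive_rate, x$accuracy))
  invisible(x)
}

#' Tidy classification metrics
#' @param x a `pges_metrics`.
#' @param ... unused.
#' @return per-class tibble of precision/recall/F1.
#' @export
tidy.pges_metrics <- function(x, ...) x$metrics

#' One-row metric summary
#' @param x a `pges_metrics`.
#' @param ... unused.
#' @return tibble with accuracy, FPR and the suppression-class F1.
#' @export
glance.pges_metrics <- function(x, ...) {
  tibble(
    accuracy = x$accuracy,
    false_positive_rate = x$false_positive_rate,
    f1_pges = x$metrics$f1[x$metrics$class == "pges"],
    f1_background = x$metrics$f1[x$metrics$class == "background"],
    degenerate = x$degenerate
  )
}

#' Event-level detection rate
#'
#' An annotated suppression event counts as detected when at least one
#' positive epoch prediction overlaps its interval on either channel.
#'
#' @param events tibble of annotated events with `session_id`, `start_s`,
#'   `end_s` (one row per event).
#' @param predictions tibble of epoch predictions with `session_id`,
#'   `channel`, `start_s`, `pred` (0/1).
#' @param window_s epoch window length in seconds.
#' @return detection fraction in `[0, 1]`.
#' @export
event_detection_rate <- function(events, predictions, window_s = 5) {
  if (nrow(events) == 0) abort("no annotated events supplied.")
  hits <- purrr::pmap_lgl(
    events[, c("session_id", "start_s", "end_s")],
    function(session_id, start_s, end_s) {
      pr <- predictions[predictions$session_id == session_id &
                          predictions$pred == 1, ]
      if (nrow(pr) == 0) return(FALSE)
      any(pr$start_s < end_s & pr$start_s + window_s > start_s)
    }
  )
  mean(hits)
}

#' Learning curve over training-cohort size
#'
#' Trains one model per requested number of training patients (holding the
#' validation set fixed) and records the final-epoch training and validation
#' losses. Patients are added in their order in `train_patients`, so the
#' curve is nested and reproducible for a fixed seed.
#'
#' @param features scaled feature tibble (all patients).
#' @param train_patients character vector of training patient ids, in
#'   inclusion order.
#' @param val_patients character vector of validation patient ids.
#' @param sizes integer vector of training-cohort sizes (each >= 1, at most
#'   `length(train_patients)`).
#' @param cfg a [vae_config()].
#' @return tibble with `size`, `train_loss`, `val_loss`.
#' @export
learning_curve <- function(features, train_patients, val_patients,
                           sizes, cfg = vae_config()) {
  if (any(sizes > length(train_patients))) {
    abort("a requested size exceeds the number of available training patients.")
  }
  if (any(sizes < 1)) abort("sizes must be >= 1.")
  val <- features[features$patient_id %in% val_patients, ]
  purrr::map_dfr(sizes, function(k) {
    tr <- features[features$patient_id %in% train_patients[seq_len(k)], ]
    fit <- vae_train(tr, val, cfg)
    h <- fit$loss_history
    tibble(size = k, train_loss = h$train_loss[nrow(h)],
           val_loss = h$val_loss[nrow(h)])
  })
}
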