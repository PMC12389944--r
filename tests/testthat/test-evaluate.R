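test_that("classification metrics match hand-counted examples", {
  m <- classification_metrics(c(1, 1, 0, 0), c(1, 0, 1, 0))
  pg <- m$metrics[m$metrics$class == "pges", ]
  expect_equal(pg$precision, 0.5)
  expect_equal(pg$recall, 0.5)
  expect_equal(m$false_positive_rate, 0.5)

  perfect <- classification_metrics(c(0, 1, 1, 0), c(0, 1, 1, 0))
  expect_true(all(perfect$metrics$f1 == 1))
  expect_equal(perfect$false_positive_rate, 0)

  all1 <- classification_metrics(c(0, 1, 0, 1), c(1, 1, 1, 1))
  pg1 <- all1$metrics[all1$metrics$class == "pges", ]
  expect_equal(pg1$recall, 1)
  expect_equal(all1$false_positive_rate, 1)
  expect_true(all1$degenerate)                        # background precision 0/0

  expect_error(classification_metrics(c(1, 0), 1), "length")
})

test_that("metrics agree with the direct-count oracle on random vectors", {
  set.seed(13)
  for (i in 1:30) {
    yt <- rbinom(60, 1, 0.4)
    yp <- rbinom(60, 1, 0.5)
    m <- classification_metrics(yt, yp)
    for (cls in c(0, 1)) {
      want <- metrics_oracle(yt, yp, positive = cls)
      got <- m$metrics[m$metrics$class == ifelse(cls == 1, "pges", "background"), ]
      expect_equal(got$precision, unname(want["precision"]))
      expect_equal(got$recall, unname(want["recall"]))
      expect_equal(got$f1, unname(want["f1"]))
    }
    expect_equal(sum(m$confusion), 60)
  }
})

test_that("normalised confusion rows/columns sum to one where defined", {
  m <- classification_metrics(rbinom(50, 1, 0.3), rbinom(50, 1, 0.5))
  expect_equal(unname(rowSums(m$confusion_row_norm)), c(1, 1))
  expect_equal(unname(colSums(m$confusion_col_norm)), c(1, 1))
})

test_that("event detection counts interval-overlapping positives", {
  events <- tibble::tibble(session_id = c("S1", "S2"),
                           start_s = c(10, 5), end_s = c(30, 20))
  preds <- tibble::tibble(
    session_id = c("S1", "S1", "S2"),
    channel = "A",
    start_s = c(12.5, 50, 100),
    pred = c(1, 1, 1)
  )
  expect_equal(event_detection_rate(events, preds), 0.5)   # only S1 overlaps
  preds$pred <- 0
  expect_equal(event_detection_rate(events, preds), 0)
  # epoch starting just before the event still overlaps via its window
  p2 <- tibble::tibble(session_id = "S1", channel = "A", start_s = 7.5, pred = 1)
  expect_equal(event_detection_rate(events[1, ], p2, window_s = 5), 1)
  expect_error(event_detection_rate(events[0, ], preds), "no annotated")
})

test_that("learning curve trains one model per size, reproducibly", {
  set.seed(14)
  feats <- tibble::as_tibble(matrix(runif(120 * 14), 120,
                                    dimnames = list(NULL, feature_names())))
  feats$patient_id <- rep(sprintf("P%02d", 1:6), each = 20)
  cfg <- vae_config(epochs = 3, seed = 14)
  lc <- learning_curve(feats, sprintf("P%02d", 1:4), sprintf("P%02d", 5:6),
                       sizes = c(2, 4), cfg = cfg)
  expect_equal(lc$size, c(2, 4))
  expect_true(all(is.finite(lc$train_loss)))
  expect_true(all(is.finite(lc$val_loss)))
  lc2 <- learning_curve(feats, sprintf("P%02d", 1:4), sprintf("P%02d", 5:6),
                        sizes = c(2, 4), cfg = cfg)
  expect_identical(lc, lc2)
  expect_error(
    learning_curve(feats, sprintf("P%02d", 1:4), "P05", sizes = 5, cfg = cfg),
    "exceeds"
  )
})
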