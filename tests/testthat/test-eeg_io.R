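test_that("tabular write/read round-trips signal, rate and annotations", {
  ann <- ann_tbl(list(5, 8, "seizure"), list(10, 14, "pges"))
  rec <- make_recording(2, duration_s = 20, fs = 50, annotations = ann)
  path <- file.path(withr::local_tempdir(), "P01_S01.csv")
  write_recording(rec, path)
  rec2 <- read_recording(path)
  expect_equal(rec2$sample_rate, 50)
  expect_equal(rec2$channels, rec$channels)
  expect_equal(rec2$signal, rec$signal, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(rec2$annotations, rec$annotations)
  expect_equal(rec2$patient_id, "P01")
  expect_equal(rec2$session_id, "S01")
})

test_that("EDF write/read round-trips to writer precision", {
  rec <- make_recording(3, duration_s = 4, fs = 128,
                        channels = c("FP2", "T8", "F8"))
  path <- file.path(withr::local_tempdir(), "P02_S01.edf")
  write_edf(rec, path)
  out <- read_edf(path)
  expect_equal(out$sample_rate, 128)
  expect_equal(out$channels, c("FP2", "T8", "F8"))
  # 16-bit quantisation over the physical range
  rng <- max(abs(range(rec$signal)))
  expect_lt(max(abs(out$signal - rec$signal)), 2 * rng / 65536 + 1e-3)
})

test_that("unit handling: mV converts, missing metadata errors", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "a.csv")
  writeLines(c("sample_rate=10 unit=mV", "A", "1", "2"), p)
  rec <- read_recording(p)
  expect_equal(as.numeric(rec$signal), c(1000, 2000))

  p2 <- file.path(dir, "b.csv")
  writeLines(c("unit=uV", "A", "1"), p2)
  expect_error(read_recording(p2), class = "pgesr_unit_error")
  p3 <- file.path(dir, "c.csv")
  writeLines(c("sample_rate=10", "A", "1"), p3)
  expect_error(read_recording(p3), class = "pgesr_unit_error")
})

test_that("bipolar montage subtracts the reference and honours aliases", {
  rec <- make_recording(3, duration_s = 2, fs = 100,
                        channels = c("FP2", "T8", "F8"))
  bi <- make_bipolar(rec, c("FP2", "T4"), "F8")
  expect_equal(bi$channels, c("FP2-F8", "T8-F8"))
  expect_equal(bi$signal[1, ], rec$signal[1, ] - rec$signal[3, ])
  expect_equal(bi$signal[2, ], rec$signal[2, ] - rec$signal[3, ])
  # anode == reference gives an all-zero channel
  z <- make_bipolar(rec, "F8", "F8")
  expect_true(all(z$signal == 0))
  expect_error(make_bipolar(rec, "CZ", "F8"), class = "pgesr_channel_error")
})

test_that("bipolar montage is invariant to a common added signal", {
  rec <- make_recording(3, duration_s = 2, fs = 100,
                        channels = c("FP2", "T8", "F8"))
  common <- sin(2 * pi * 3 * seq_len(ncol(rec$signal)) / 100) * 17 + 5
  rec2 <- rec
  rec2$signal <- rec$signal + matrix(common, 3, ncol(rec$signal), byrow = TRUE)
  b1 <- make_bipolar(rec, c("FP2", "T8"), "F8")
  b2 <- make_bipolar(rec2, c("FP2", "T8"), "F8")
  expect_equal(b1$signal, b2$signal, tolerance = 1e-10)
})

test_that("excision removes samples, re-times annotations, records cuts", {
  ann <- ann_tbl(list(40, 60, "seizure"), list(60, 80, "pges"))
  rec <- make_recording(1, duration_s = 100, fs = 10, annotations = ann)
  out <- excise_intervals(rec, "seizure")
  expect_equal(ncol(out$signal), 800)               # 100 s - 20 s at 10 Hz
  pg <- out$annotations[out$annotations$label == "pges", ]
  expect_equal(pg$start_s, 40)
  expect_equal(pg$end_s, 60)
  expect_equal(out$cuts, 40)
  # signal content: sample after the cut was originally at 60 s
  expect_equal(out$signal[1, 401], rec$signal[1, 601])
})

test_that("excision merges overlapping intervals and conserves counts", {
  ann <- ann_tbl(list(10, 30, "seizure"), list(20, 40, "seizure"))
  rec <- make_recording(1, duration_s = 100, fs = 10, annotations = ann)
  out <- excise_intervals(rec, "seizure")
  expect_equal(ncol(out$signal), 1000 - 300)        # merged [10,40) = 30 s
  expect_equal(out$cuts, 10)
})

test_that("excision degenerate cases", {
  rec0 <- make_recording(1, duration_s = 10, fs = 10)
  expect_identical(excise_intervals(rec0, "seizure"), rec0)

  ann <- ann_tbl(list(0, 10, "seizure"))
  rec1 <- make_recording(1, duration_s = 10, fs = 10, annotations = ann)
  expect_error(excise_intervals(rec1, "seizure"), "entire recording")
})

test_that("annotation validation rejects bad labels and inverted intervals", {
  expect_error(
    eeg_recording(matrix(0, 1, 100), 10, "A",
                  annotations = ann_tbl(list(1, 2, "artifact"))),
    "labels"
  )
  expect_error(
    eeg_recording(matrix(0, 1, 100), 10, "A",
                  annotations = ann_tbl(list(3, 2, "pges"))),
    "start_s < end_s"
  )
  expect_error(
    eeg_recording(matrix(0, 1, 100), 10, "A",
                  annotations = ann_tbl(list(5, 20, "pges"))),
    "within"
  )
})
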