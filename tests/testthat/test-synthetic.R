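test_that("synthetic sessions honour the amplitude contrast and annotations", {
  cfg <- synthetic_config()
  rec <- generate_session(cfg, seed = 21)
  fs <- rec$sample_rate
  pg <- rec$annotations[rec$annotations$label == "pges", ]
  sz <- rec$annotations[rec$annotations$label == "seizure", ]
  expect_equal(nrow(pg), 1)
  expect_equal(nrow(sz), 1)
  expect_gte(pg$start_s, sz$end_s)
  expect_lte(pg$start_s, sz$end_s + 30)               # onset within 30 s

  # suppressed segment (excluding tapers) well under 10 uV RMS
  i <- (round(pg$start_s * fs) + 2 * fs):(round(pg$end_s * fs) - 2 * fs)
  expect_lt(sqrt(mean(rec$signal[1, i]^2)), 10)
  expect_lt(sqrt(mean(rec$signal[1, i]^2)), cfg$suppression_rms_uv * 1.1)
  # background within 20% of target (patient factor 1)
  j <- 1:(20 * fs)
  expect_lt(abs(sqrt(mean(rec$signal[1, j]^2)) - cfg$background_rms_uv),
            0.2 * cfg$background_rms_uv)
})

test_that("session generation is deterministic per seed", {
  cfg <- small_cohort_config()
  a <- generate_session(cfg, seed = 5)
  b <- generate_session(cfg, seed = 5)
  expect_identical(a, b)
  c_ <- generate_session(cfg, seed = 6)
  expect_false(identical(a$signal, c_$signal))
})

test_that("zero-contrast negative control generates, excess rejected", {
  expect_error(synthetic_config(suppression_rms_uv = 36), "not exceed")
  cfg <- synthetic_config(suppression_rms_uv = 35)
  rec <- generate_session(cfg, seed = 3)
  pg <- rec$annotations[rec$annotations$label == "pges", ]
  fs <- rec$sample_rate
  i <- (round(pg$start_s * fs) + 2 * fs):(round(pg$end_s * fs) - 2 * fs)
  j <- 1:(20 * fs)
  rms_in <- sqrt(mean(rec$signal[1, i]^2))
  rms_out <- sqrt(mean(rec$signal[1, j]^2))
  expect_lt(abs(rms_in - rms_out) / rms_out, 0.35)    # no real contrast
})

test_that("cohorts give the requested disjoint patient splits", {
  coh <- generate_cohort(synthetic_config(sessions_per_patient = 1))
  expect_length(coh$recordings, 26)
  expect_length(coh$split$train, 10)
  expect_length(coh$split$val, 7)
  expect_length(coh$split$test, 9)
  expect_length(
    intersect(coh$split$train, union(coh$split$val, coh$split$test)), 0
  )
  expect_length(intersect(coh$split$val, coh$split$test), 0)
  # val/test sessions always carry suppression; training is mostly background
  m <- coh$manifest
  expect_true(all(m$has_pges[m$split != "train"]))
  expect_lt(mean(m$has_pges[m$split == "train"]), 1)
  # determinism
  coh2 <- generate_cohort(synthetic_config(sessions_per_patient = 1))
  expect_identical(coh$recordings[[1]]$signal, coh2$recordings[[1]]$signal)
})

test_that("suppression durations follow the configured distribution", {
  cfg <- synthetic_config()
  set.seed(31)
  draws <- replicate(1000, pgesr:::rtruncnorm1(cfg$pges_duration_mean_s,
                                               cfg$pges_duration_sd_s, 1))
  expect_lt(abs(mean(draws) - 27.1), 0.3)             # 3 x MC standard error
  expect_lt(abs(sd(draws) - 2.6), 0.3)
  expect_true(all(draws >= 1))
})

test_that("mini-cohort and config validation", {
  cfg <- synthetic_config(n_patients = 3, sessions_per_patient = 1,
                          split_sizes = c(train = 1, val = 1, test = 1),
                          pre_s = 20, post_s = 30)
  coh <- generate_cohort(cfg)
  expect_length(coh$recordings, 3)
  expect_error(
    synthetic_config(n_patients = 2),
    "split"
  )
})

test_that("a cohort can be written to disk and read back", {
  cfg <- synthetic_config(n_patients = 3, sessions_per_patient = 1,
                          split_sizes = c(train = 1, val = 1, test = 1),
                          pre_s = 10, post_s = 20, seizure_duration_s = 5)
  coh <- generate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  rec <- coh$recordings[[1]]
  back <- read_recording(file.path(dir, sprintf("%s_%s.csv", rec$patient_id,
                                                rec$session_id)))
  expect_equal(back$signal, rec$signal, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(nrow(back$annotations), nrow(rec$annotations))
})
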