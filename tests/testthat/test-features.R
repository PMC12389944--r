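test_that("epoch grid: counts, boundary cases, trailing partial discarded", {
  spec <- feature_spec()
  ep <- epochize(make_recording(2, duration_s = 20, fs = 100), spec)
  expect_equal(nrow(ep), 2 * 7)                       # floor((20-5)/2.5)+1
  expect_equal(sort(unique(ep$start_s)), seq(0, 15, by = 2.5))
  expect_equal(nrow(epochize(make_recording(1, 5, 100), spec)), 1)
  expect_warning(
    ep0 <- epochize(make_recording(1, 4.9, 100), spec),
    "shorter"
  )
  expect_equal(nrow(ep0), 0)
})

test_that("epochs never span a splice cut-point", {
  ann <- ann_tbl(list(10, 12, "seizure"))
  rec <- make_recording(1, duration_s = 22, fs = 100, annotations = ann)
  cut_rec <- excise_intervals(rec, "seizure")         # 20 s, cut at 10 s
  ep <- epochize(cut_rec, feature_spec())
  spans <- ep$start_s < 10 & ep$start_s + 5 > 10
  expect_true(all(!spans))
  # starts at 5 (window [5,10)) and 10 (window [10,15)) survive
  expect_true(all(c(5, 10) %in% ep$start_s))
  expect_false(7.5 %in% ep$start_s)
})

test_that("epoch labelling uses the majority-overlap rule", {
  pg <- tibble::tibble(start_s = 10, end_s = 40)
  expect_equal(label_epoch(10, 5, pg), 1L)            # fully inside
  expect_equal(label_epoch(0, 5, pg), 0L)             # no overlap
  pg2 <- tibble::tibble(start_s = 14, end_s = 40)
  expect_equal(label_epoch(10, 5, pg2), 0L)           # 1 s < 2.5 s
  pg3 <- tibble::tibble(start_s = 12.5, end_s = 40)
  expect_equal(label_epoch(10, 5, pg3), 1L)           # exactly half counts
  expect_equal(label_epoch(10, 5, NULL), 0L)
})

test_that("rectified time statistics match hand arithmetic", {
  tf <- time_features(c(3, -4, 0))
  expect_equal(unname(tf), c(7 / 3, sd(c(3, 4, 0)), 3, 4, 0))
  tfc <- time_features(rep(-5, 10))
  expect_equal(unname(tfc), c(5, 0, 5, 5, 5))
  # positive rescaling scales every statistic linearly
  x <- rnorm(50)
  expect_equal(unname(time_features(3 * x)), unname(3 * time_features(x)))
})

test_that("band powers: spectral concentration and the sum-to-one rule", {
  fs <- 207
  t <- (0:1034) / fs
  bp <- band_powers(30 * sin(2 * pi * 10 * t), fs)
  expect_gt(bp[["rel_alpha"]], 0.9)
  expect_equal(sum(bp[5:8]), 1, tolerance = 1e-9)

  z <- band_powers(rep(0, 1035), fs)
  expect_equal(unname(z), rep(0, 8))

  two <- 20 * sin(2 * pi * 2 * t) + 20 * sin(2 * pi * 20 * t)
  bp2 <- band_powers(two, fs)
  expect_equal(bp2[["rel_delta"]], 0.5, tolerance = 0.05)
  expect_equal(bp2[["rel_beta"]], 0.5, tolerance = 0.05)
  expect_error(band_powers(t, 60), "twice the highest")
})

test_that("Petrosian fractal dimension: formula cases and invariances", {
  expect_equal(petrosian_fd(1:100), 1)                # monotone ramp
  alt <- rep(c(1, -1), 50)                            # N = 100, Ndelta = 98
  expected <- log10(100) / (log10(100) + log10(100 / (100 + 0.4 * 98)))
  expect_equal(petrosian_fd(alt), expected)
  set.seed(4)
  noise <- rnorm(1035)
  tone <- sin(2 * pi * 10 * (0:1034) / 207)
  expect_gt(petrosian_fd(noise), petrosian_fd(tone))
  expect_equal(petrosian_fd(5 * noise), petrosian_fd(noise))
  expect_error(petrosian_fd(c(1, 2)), "at least 3")
})

test_that("feature table has 14 ordered features and correct labels", {
  ann <- ann_tbl(list(0, 20, "pges"))
  rec <- make_recording(2, duration_s = 20, fs = 207, annotations = ann)
  ft <- build_feature_table(rec)
  expect_equal(nrow(ft), 14)
  expect_equal(
    names(ft),
    c("patient_id", "session_id", "channel", "start_s", feature_names(), "label")
  )
  expect_true(all(ft$label == 1))
  rel <- as.matrix(ft[, c("rel_delta", "rel_theta", "rel_alpha", "rel_beta")])
  expect_equal(unname(rowSums(rel)), rep(1, 14), tolerance = 1e-9)
})

test_that("min-max scaling maps training data into [0,1] and clips", {
  set.seed(5)
  tr <- tibble::as_tibble(matrix(rnorm(40 * 14), 40,
                                 dimnames = list(NULL, feature_names())))
  tr$const <- NULL
  sc <- fit_minmax(tr)
  trs <- apply_minmax(tr, sc)
  m <- as.matrix(trs[, feature_names()])
  expect_true(all(m >= 0 & m <= 1))
  expect_equal(max(m), 1)
  expect_equal(min(m), 0)

  te <- tr
  te$abs_mean <- te$abs_mean - 100                    # below training min
  tes <- apply_minmax(te, sc)
  expect_true(all(tes$abs_mean == 0))

  tr2 <- tr
  tr2$pfd <- 1                                        # constant feature
  sc2 <- fit_minmax(tr2)
  expect_true(all(apply_minmax(tr2, sc2)$pfd == 0))
})
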