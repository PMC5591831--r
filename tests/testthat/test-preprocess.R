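test_that("initial dynamics are dropped in units of TR", {
  # 185 volumes at TR = 3 s, drop 5 -> 180 remain
  ts <- make_ts(matrix(rnorm(2 * 185), 2), fs = 1 / 3, modality = "fmri")
  out <- drop_initial_dynamics(ts, 5)
  expect_identical(ncol(out$values), 180L)
  # n = 0 is the identity
  expect_identical(drop_initial_dynamics(ts, 0)$values, ts$values)
  # EEG at 250 Hz: 5 dynamics x 3 s x 250 Hz = 3750 samples
  eeg <- make_ts(matrix(rnorm(2 * 5000), 2), fs = 250)
  out2 <- drop_initial_dynamics(eeg, 5, tr_s = 3)
  expect_identical(ncol(out2$values), 5000L - 3750L)
  short <- make_ts(matrix(rnorm(2 * 10), 2), fs = 250)
  expect_error(drop_initial_dynamics(short, 5, tr_s = 3), "too short")
})

test_that("band-pass keeps in-band tones and suppresses out-of-band ones", {
  fs <- 250
  t <- seq(0, 60, by = 1 / fs)
  tone10 <- sin(2 * pi * 10 * t)
  ts <- make_ts(rbind(tone10, tone10), fs = fs)
  in_band <- bandpass_filter(ts, 8, 13)
  expect_gte(sd(in_band$values[1, ]) / sd(tone10), 0.95)
  out_band <- bandpass_filter(ts, 4, 8)
  expect_lte(sd(out_band$values[1, ]) / sd(tone10), 0.1)
  zero <- make_ts(matrix(0, 2, 1000), fs = fs)
  expect_equal(max(abs(bandpass_filter(zero, 8, 13)$values)), 0)
  expect_error(bandpass_filter(ts, 13, 8), "invalid band edges")
  expect_error(bandpass_filter(ts, 0, 13), "invalid band edges")
})

test_that("filtering is zero-phase: a symmetric pulse stays symmetric", {
  fs <- 250
  n <- 1001
  pulse <- exp(-((seq_len(n) - 501)^2) / (2 * 20^2))
  ts <- make_ts(matrix(pulse, 1), fs = fs)
  y <- bandpass_filter(ts, 2, 40)$values[1, ]
  # symmetric to within a tiny fraction of the peak (boundary transients
  # aside, forward-backward filtering introduces no group delay)
  expect_lt(max(abs(y - rev(y))), 1e-3 * max(abs(y)))
  expect_identical(which.max(abs(y)), 501L)
})

test_that("band splitting returns one copy per band with energy in place", {
  fs <- 250
  t <- seq(0, 30, by = 1 / fs)
  mixed <- sin(2 * pi * 6 * t) + sin(2 * pi * 25 * t)
  ts <- make_ts(rbind(mixed, mixed), fs = fs)
  out <- split_bands(ts)
  expect_identical(names(out), c("theta", "alpha", "beta1", "beta2"))
  band_power <- vapply(out, function(b) mean(b$values[1, ]^2), numeric(1))
  # the 6 Hz component lands in theta, the 25 Hz component in beta2
  expect_gt(band_power["theta"], 10 * band_power["alpha"])
  expect_gt(band_power["beta2"], 10 * band_power["beta1"])
  expect_identical(split_bands(ts, list()), list())
})

test_that("epoching forms, rejects and accounts for epochs correctly", {
  fs <- 250
  # 540 s at 250 Hz in 3-s epochs -> 180 epochs
  quiet <- make_ts(matrix(rnorm(2 * 540 * fs), 2), fs = fs)
  res <- epoch_and_reject(quiet, 3, 150)
  expect_identical(res$report$n_total, 180L)
  # a 200 uV step on one channel in one epoch is rejected at 150 uV
  x <- matrix(rnorm(2 * 10 * 3 * fs), 2)
  x[2, (5 * 3 * fs + 1):(5 * 3 * fs + 100)] <- 200
  res2 <- epoch_and_reject(make_ts(x, fs = fs), 3, 150)
  expect_true(6 %in% res2$report$rejected_indices)
  expect_identical(res2$report$n_kept + res2$report$n_rejected,
                   res2$report$n_total)
  # all-zero recording: nothing rejected, partial trailing epoch dropped
  zeros <- make_ts(matrix(0, 2, 10 * 3 * fs + 100), fs = fs)
  res3 <- epoch_and_reject(zeros, 3, 150)
  expect_identical(res3$report$n_rejected, 0L)
  expect_identical(ncol(res3$ts$values), 7500L)
  # everything over threshold is an explicit failure
  loud <- make_ts(matrix(c(-200, 200), 1, 3 * fs * 2), fs = fs)
  expect_error(epoch_and_reject(loud, 3, 150), "rejected")
})

test_that("epoch accounting identity holds on random inputs", {
  fs <- 100
  set.seed(42)
  for (rep in 1:20) {
    n_ep <- sample(3:12, 1)
    x <- matrix(rnorm(3 * n_ep * fs, sd = 20), 3)
    res <- epoch_and_reject(make_ts(x, fs = fs), 1, 150)
    expect_identical(res$report$n_kept + res$report$n_rejected,
                     res$report$n_total)
    expect_identical(ncol(res$ts$values), as.integer(res$report$n_kept * fs))
  }
})

test_that("nuisance regression produces orthogonal residuals, idempotently", {
  set.seed(1)
  conf <- cbind(rnorm(200), rnorm(200))
  signal <- matrix(rnorm(3 * 200), 3)
  signal[1, ] <- conf[, 1]                      # channel equal to a confound
  signal[2, ] <- conf[, 2] + rnorm(200)         # confound plus noise
  ts <- make_ts(signal, fs = 1 / 3, modality = "fmri")
  out <- regress_nuisance(ts, conf)
  expect_lt(max(abs(out$values[1, ])), 1e-10)
  expect_lt(abs(cor(out$values[2, ], conf[, 2])), 1e-10)
  expect_lt(abs(cor(out$values[3, ], conf[, 1])), 1e-10)
  # intercept-only regression demeans
  demeaned <- regress_nuisance(ts, NULL)
  expect_equal(demeaned$values, signal - rowMeans(signal), tolerance = 1e-12,
               ignore_attr = TRUE)
  # idempotence
  twice <- regress_nuisance(out, conf)
  expect_lt(max(abs(twice$values - out$values)), 1e-10)
  expect_error(regress_nuisance(ts, cbind(conf[, 1], conf[, 1])),
               "rank-deficient")
  expect_error(regress_nuisance(ts, conf[1:10, ]), "match sample count")
})

test_that("sphere-ROI extraction averages the right voxels", {
  vox_xyz <- rbind(c(0, 0, 0), c(3, 0, 0), c(20, 0, 0))
  vals <- rbind(c(1, 1), c(3, 5), c(100, 100))
  vts <- make_ts(vals, fs = 1 / 3, modality = "fmri")
  rois <- data.frame(label = c("A", "B"), x_mm = c(1, 20), y_mm = 0, z_mm = 0)
  out <- extract_roi_timeseries(vts, vox_xyz, rois, radius_mm = 5)
  expect_equal(out$values["A", ], c(2, 3), ignore_attr = TRUE)  # mean of 1,3 / 1,5
  expect_equal(out$values["B", ], c(100, 100), ignore_attr = TRUE)
  # default radius is 5 mm
  expect_identical(formals(extract_roi_timeseries)$radius_mm, 5)
  # empty ROI flagged, not dropped
  rois2 <- rbind(rois, data.frame(label = "C", x_mm = -50, y_mm = 0, z_mm = 0))
  expect_warning(out2 <- extract_roi_timeseries(vts, vox_xyz, rois2, 5),
                 "zero voxels")
  expect_identical(attr(out2, "empty_rois"), "C")
  expect_identical(nrow(out2$values), 3L)
})

test_that("ROI extraction is invariant to voxel ordering", {
  set.seed(8)
  vox_xyz <- matrix(runif(30 * 3, -10, 10), 30)
  vals <- matrix(rnorm(30 * 6), 30)
  rois <- data.frame(label = c("A", "B"), x_mm = c(0, 5), y_mm = c(0, -2),
                     z_mm = c(0, 3))
  perm <- sample(30)
  a <- extract_roi_timeseries(make_ts(vals, 1 / 3, "fmri"), vox_xyz, rois, 6)
  b <- extract_roi_timeseries(make_ts(vals[perm, ], 1 / 3, "fmri"),
                              vox_xyz[perm, ], rois, 6)
  expect_equal(a$values, b$values, tolerance = 1e-12)
})
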