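# Signal path: filtering, differentiation, magnitude, spectra.

# a wearable trial whose "hand" x-axis is replaced by a chosen series
trial_with_series <- function(x, device = "wearable") {
  prof <- device_profile(device)
  n <- length(x)
  channels <- setNames(lapply(prof$channels, function(ch)
    matrix(0, n, 3, dimnames = list(NULL, c("x", "y", "z")))),
    prof$channels)
  channels[["hand"]][, 1] <- x
  # non-degenerate second channel so validation is representative
  channels[["forearm"]][, 2] <- seq_len(n) * 1e-3
  motion_trial("S1", device, "glass", 1L, channels)
}

test_that("zero-phase Butterworth has documented gain structure", {
  fs <- 60; fc <- 10
  t <- (0:(fs * 30 - 1)) / fs

  # DC gain 1: constants pass untouched (away from the edge transients of
  # the forward-backward pass)
  tr <- trial_with_series(rep(7, length(t)))
  f <- butterworth_lowpass(tr, fc)
  interior <- f$channels[["hand"]][(length(t) / 4):(3 * length(t) / 4), 1]
  expect_equal(interior, rep(7, length(interior)), tolerance = 1e-6)
  expect_true(f$filter$zero_phase)

  # amplitude 0.5 +/- 0.02 at the cutoff (single-pass -3 dB applied twice)
  f <- butterworth_lowpass(trial_with_series(sin(2 * pi * fc * t)), fc)
  mid <- f$channels[["hand"]][(length(t) / 3):(2 * length(t) / 3), 1]
  amp <- fit_amplitude(mid, fc, fs)
  expect_lt(abs(amp - 0.5), 0.02)

  # deep passband: gain >= 0.999
  f <- butterworth_lowpass(trial_with_series(sin(2 * pi * 0.1 * fc * t)), fc)
  mid <- f$channels[["hand"]][(length(t) / 3):(2 * length(t) / 3), 1]
  expect_gte(fit_amplitude(mid, 0.1 * fc, fs), 0.999)

  expect_error(butterworth_lowpass(tr, 30), "cutoff")
})

test_that("acceleration is exact on quadratics and accurate on sinusoids", {
  fs <- 60
  t <- (0:(fs * 4 - 1)) / fs

  tr <- trial_with_series(rep(3, length(t)))
  acc <- derive_acceleration(tr)
  expect_equal(max(abs(acc[["hand"]])), 0, tolerance = 1e-9)

  # x = a t^2 / 2 with a = 3 mm/s^2: interior second difference is exact
  tr <- trial_with_series(0.5 * 3 * t^2)
  acc <- derive_acceleration(tr)[["hand"]][, 1]
  interior <- acc[2:(length(acc) - 1)]
  expect_equal(interior, rep(3, length(interior)), tolerance = 1e-8)

  # 1 Hz unit sinusoid: |a| = (2 pi)^2 within 0.5% (discretization bound)
  tr <- trial_with_series(sin(2 * pi * 1 * t))
  acc <- derive_acceleration(tr)[["hand"]][, 1]
  amp <- fit_amplitude(acc[5:(length(acc) - 4)], 1, fs)
  expect_lt(abs(amp - (2 * pi)^2) / (2 * pi)^2, 0.005)
})

test_that("3D magnitude is the per-step norm and rotation invariant", {
  m <- matrix(rep(c(3, 4, 0), each = 10), 10, 3)
  expect_equal(magnitude_1d(m)$values, rep(5, 10))
  expect_equal(magnitude_1d(matrix(0, 8, 3))$values, rep(0, 8))

  set.seed(2)
  xyz <- matrix(rnorm(60), 20, 3)
  for (s in 1:5) {
    R <- random_rotation(s)
    expect_equal(magnitude_1d(xyz %*% R)$values, magnitude_1d(xyz)$values,
                 tolerance = 1e-9)
  }
  expect_error(magnitude_1d(matrix(c(NA, rnorm(29)), 10, 3)), "finite")
})

test_that("spectral features behave: Parseval, dominant bin, guards", {
  # Parseval on the two-sided spectrum vs direct time-domain sum
  set.seed(3)
  for (n in c(32L, 100L, 333L)) {
    x <- rnorm(n)
    mag <- dft_magnitude(x)
    xc <- x - mean(x)
    expect_equal(sum(mag^2), n * sum(xc^2), tolerance = 1e-6 * n * sum(xc^2))
  }

  # constant series -> zero vector via the normalization guard
  expect_equal(frequency_features(rep(2, 40), 16L), numeric(16))

  # sinusoid at an exact analysis frequency dominates its bin
  nb <- 16L
  n <- 2L * nb          # native one-sided bins coincide with the grid
  x <- sin(2 * pi * 4 * (0:(n - 1)) / n)   # 4 cycles in n samples
  v <- frequency_features(x, nb)
  expect_equal(sum(v^2), 1, tolerance = 1e-9)
  expect_gt(max(v^2), 0.99)

  expect_error(frequency_features(rnorm(10), 1L), "n_bins")
  expect_error(frequency_features(rnorm(4), 16L), "shorter")
})

test_that("feature matrix has the documented shape and determinism", {
  rec <- make_tiny_cohort(n_subjects = 2L)
  cfg <- pipeline_config(n_freq_bins = 16L)

  fm_pos <- build_feature_matrix(rec, pipeline_config(feature_kind = "position_freq"))
  expect_equal(dim(fm_pos$X), c(24L, 15L * 16L))   # 5 channels x 3 axes

  fm_acc <- build_feature_matrix(rec, pipeline_config(feature_kind = "accel_freq"))
  expect_equal(ncol(fm_acc$X), 5L * 16L + 5L)      # + per-channel mean

  fm <- build_feature_matrix(rec, cfg)
  expect_equal(ncol(fm$X), ncol(fm_pos$X) + ncol(fm_acc$X))
  expect_true(all(fm$X >= 0))
  expect_equal(nrow(fm$instance_index), 24L)

  # determinism: identical input -> identical matrix
  expect_identical(fm$X, build_feature_matrix(rec, cfg)$X)

  # camera trunk markers feed labeling, not features
  cam <- make_tiny_cohort(n_subjects = 1L, device = "camera",
                          duration_s = 0.8)
  fmc <- build_feature_matrix(cam, pipeline_config(
    device_profile = "camera", feature_kind = "position_freq"))
  expect_equal(ncol(fmc$X), 27L * 16L)
  expect_false(any(grepl("sternum|spine", fmc$feature_names)))

  # mixed profiles rejected
  expect_error(build_feature_matrix(c(rec, cam), cfg), "device")
})
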