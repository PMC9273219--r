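test_that("CSV round-trip preserves values, metadata and row order", {
  tr <- toy_traces(3, 40)
  path <- withr::local_tempfile(fileext = ".csv")
  write_traces(tr, path)
  back <- load_traces(path)
  expect_equal(back$values, tr$values, ignore_attr = TRUE)
  expect_equal(back$sampling_rate, tr$sampling_rate)
  expect_equal(back$condition, tr$condition)
  expect_equal(n_neurons(back), 3L)
  expect_equal(n_frames(back), 40L)
})

test_that("HDF5 round-trip is bit-identical for a 120x1200 matrix", {
  set.seed(42)
  vals <- matrix(runif(120 * 1200, 50, 200), 120, 1200)
  tr <- calcium_traces(vals, 2, trial_id = "h5trial", condition = "day1")
  path <- withr::local_tempfile(fileext = ".h5")
  write_traces(tr, path)
  back <- load_traces(path)
  expect_identical(back$values, vals)
  expect_equal(back$sampling_rate, 2)
  expect_equal(back$trial_id, "h5trial")
})

test_that("malformed inputs are rejected with informative errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("n1,1,2,3", "n2,1,2"), path)
  expect_error(load_traces(path, metadata = list(sampling_rate_hz = 2)),
               "ragged")
  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("n1,1,2,3"), path2)
  expect_error(load_traces(path2), "sampling_rate")
  expect_error(calcium_traces(matrix(-1, 1, 4), 2), "non-negative")
  expect_error(calcium_traces(matrix(NaN, 1, 4), 2), "finite")
})

test_that("dF/F0 matches its definition in both baseline dialects", {
  # lowest-percentile dialect: 99 frames at 1.0, one at 2.0
  x <- c(rep(1, 50), 2, rep(1, 49))
  tr <- calcium_traces(matrix(x, 1), 2)
  d <- normalize_dff(tr, mode = "lowest_percentile", percentile = 0.01)
  expect_equal(d$f0, 1)
  expect_equal(max(d$dff), 1)
  # trace-mean dialect, hand-computed oracle
  tr2 <- calcium_traces(matrix(c(2, 2, 4, 4), 1), 2)
  d2 <- normalize_dff(tr2, mode = "trace_mean")
  expect_equal(d2$f0, 3)
  expect_equal(d2$dff[1, ], c(-1 / 3, -1 / 3, 1 / 3, 1 / 3))
  # constant trace is exactly zero under trace_mean
  d3 <- normalize_dff(calcium_traces(matrix(5, 2, 30), 2), mode = "trace_mean")
  expect_true(all(d3$dff == 0))
})

test_that("dF/F0 is scale-invariant and invertible", {
  tr <- toy_traces(3, 150)
  for (mode in c("lowest_percentile", "trace_mean")) {
    d1 <- normalize_dff(tr, mode = mode)
    scaled <- calcium_traces(tr$values * 7.3, tr$sampling_rate)
    d2 <- normalize_dff(scaled, mode = mode)
    expect_equal(d1$dff, d2$dff, tolerance = 1e-12)
    # un-normalize: dff*f0 + f0 reconstructs the raw trace
    rec <- sweep(d1$dff, 1, d1$f0, "*") + d1$f0
    expect_equal(rec, tr$values, tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("lowest-percentile baseline uses ceiling(p*frames) samples", {
  x <- c(0, 1, rep(10, 98))  # 100 frames; 2% -> 2 lowest values
  tr <- calcium_traces(matrix(x + 1, 1), 2)
  d <- normalize_dff(tr, mode = "lowest_percentile", percentile = 0.02)
  expect_equal(d$f0, mean(c(1, 2)))
  # 1% of 100 -> exactly 1 sample
  d1 <- normalize_dff(tr, mode = "lowest_percentile", percentile = 0.01)
  expect_equal(d1$f0, 1)
})

test_that("SNR formulas and scale invariance hold", {
  fs <- 2
  # manual: amplitude ratio 10 -> 20 dB
  x <- c(rep(1, 40), rep(10, 40))
  r <- compute_snr(x, "manual_amplitude", fs,
                   signal_window = 41:80, noise_window = 1:40)
  expect_equal(r$snr_db, 20)
  # automated on a constant trace -> 0 dB
  r0 <- compute_snr(rep(0.5, 100), "automated_power", fs, window_s = 10)
  expect_equal(r0$snr_db, 0)
  # square wave 10 s at 0.1 then 10 s at 1.0: power ratio 100 -> 20 dB
  sq <- c(rep(0.1, 20), rep(1, 20))
  r2 <- compute_snr(sq, "automated_power", fs, window_s = 10)
  expect_equal(r2$snr_db, 20)
  # dB scale invariance
  r3 <- compute_snr(sq * 13, "automated_power", fs, window_s = 10)
  expect_equal(r3$snr_db, r2$snr_db, tolerance = 1e-12)
  expect_error(compute_snr(rep(0, 100), "automated_power", fs), "zero")
})

test_that("TV differentiation recovers ramps exactly and handles noise", {
  fs <- 2
  t <- seq(0, 60, by = 1 / fs)
  d <- tv_differentiate(matrix(0.5 * t, 1), sampling_rate = fs)
  interior <- 5:(length(t) - 5)
  expect_lt(max(abs(d$ddt[1, interior] - 0.5)), 1e-3)
  # constant trace -> zero derivative
  d0 <- tv_differentiate(matrix(2, 1, 100), sampling_rate = fs)
  expect_equal(max(abs(d0$ddt)), 0)
  # noisy sinusoid vs central differences of the noiseless signal
  set.seed(7)
  tt <- seq(0, 599.5, by = 0.5)
  clean <- sin(2 * pi * 0.05 * tt)
  noisy <- clean + rnorm(length(tt), 0, 0.05)
  oracle <- c(NA, diff(clean, lag = 2) / (2 * 0.5), NA)
  dn <- tv_differentiate(matrix(noisy, 1), sampling_rate = fs)
  int <- 10:(length(tt) - 10)
  rmse <- sqrt(mean((dn$ddt[1, int] - oracle[int])^2))
  expect_lt(rmse, 0.02)
})

test_that("TV differentiation commutes with negation", {
  set.seed(11)
  x <- cumsum(rnorm(300, 0, 0.1)) + 5
  a <- tv_differentiate(matrix(x, 1), sampling_rate = 2)
  b <- tv_differentiate(matrix(-x, 1), sampling_rate = 2)
  expect_equal(a$ddt, -b$ddt, tolerance = 1e-10)
})

test_that("downsampling keeps every factor-th frame and rescales the rate", {
  tr <- toy_traces(2, 1200, fs = 2)
  d2 <- downsample(tr, 2)
  expect_equal(n_frames(d2), 600L)
  expect_equal(d2$sampling_rate, 1)
  expect_equal(d2$values, tr$values[, seq(1, 1200, 2)], ignore_attr = TRUE)
  expect_identical(downsample(tr, 1), tr)
  v <- matrix(1:6, 1)
  tr6 <- calcium_traces(v, 2)
  expect_equal(as.numeric(downsample(tr6, 2)$values), c(1, 3, 5))
  expect_error(downsample(tr, 0), "positive integer")
})
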