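test_that("hysteresis detector finds square-wave transitions and stays quiet on flat traces", {
  fs <- 2
  x <- c(rep(0, 60), rep(1, 60), rep(0, 60))
  cand <- detect_transitions(x, fs, smooth_s = 0)
  expect_equal(cand$direction, c("on", "off"))
  expect_equal(cand$frame, c(61, 121), tolerance = 1)
  expect_equal(nrow(detect_transitions(rep(0.3, 100), fs)), 0L)
})

test_that("detector recovers planted bouts from a noisy synthetic trace", {
  sim <- generate_ava_trace(n_bouts = 5, noise_sd = 0.05, seed = 3)
  cand <- detect_transitions(sim$dff, 4)
  expect_equal(sum(cand$direction == "on"), 5L)
  expect_equal(sum(cand$direction == "off"), 5L)
})

test_that("tanh fit recovers transition time analytically at zero noise", {
  fs <- 4
  for (tau in c(0.25, 0.5, 1, 2, 4)) {
    t <- seq(0, 40, by = 1 / fs)
    y <- 0.1 + 1 / 2 * (1 + tanh((t - 20) / tau))
    ev <- fit_transition_tanh(y, seq_along(y), "on", fs)
    expect_true(ev$ok)
    expect_equal(ev$transition_time, 2 * tau * atanh(0.9),
                 tolerance = 1e-6)
    expect_equal(ev$tau, tau, tolerance = 1e-6)
    expect_equal(ev$amplitude, 1, tolerance = 1e-6)
  }
  # off direction
  tau <- 1.5
  t <- seq(0, 40, by = 1 / fs)
  yoff <- 0.2 + 0.8 / 2 * (1 - tanh((t - 20) / tau))
  evo <- fit_transition_tanh(yoff, seq_along(yoff), "off", fs)
  expect_equal(evo$transition_time, 2 * tau * atanh(0.9), tolerance = 1e-6)
})

test_that("transition-time estimate scales linearly with time dilation", {
  fs <- 4
  t <- seq(0, 60, by = 1 / fs)
  for (dil in c(1, 2)) {
    y <- 1 / 2 * (1 + tanh((t - 30) / (1 * dil)))
    ev <- fit_transition_tanh(y, seq_along(y), "on", fs)
    expect_equal(ev$transition_time, dil * 2 * atanh(0.9), tolerance = 1e-5)
  }
})

test_that("noisy tanh recovery is statistically efficient (near the CRLB)", {
  # at noise sd = 0.1 x amplitude, 4 Hz, tau = 1 s, the Cramer-Rao bound for
  # the four-parameter fit implies a median relative error of ~0.105 for any
  # unbiased estimator; the fit should sit within ~1.3x of that floor
  fs <- 4
  tau <- 1
  W <- 20
  t <- seq(0, W, by = 1 / fs)
  truth <- 2 * tau * atanh(0.9)
  x <- (t - W / 2) / tau
  s2 <- 1 / cosh(x)^2
  J <- cbind(1, (1 + tanh(x)) / 2, -s2 / (2 * tau), -x * s2 / (2 * tau))
  crlb_sd <- sqrt(solve(t(J) %*% J / 0.1^2)[4, 4])
  floor_median <- 0.6745 * crlb_sd / tau
  set.seed(101)
  errs <- replicate(100, {
    y <- 1 / 2 * (1 + tanh((t - W / 2) / tau)) + rnorm(length(t), 0, 0.1)
    ev <- fit_transition_tanh(y, seq_along(y), "on", fs)
    if (!isTRUE(ev$ok)) return(NA_real_)
    abs(ev$transition_time - truth) / truth
  })
  expect_lt(sum(is.na(errs)), 5)
  expect_lt(median(errs, na.rm = TRUE), 1.3 * floor_median)
  # and at lower noise the error shrinks proportionally
  set.seed(102)
  errs_lo <- replicate(50, {
    y <- 1 / 2 * (1 + tanh((t - W / 2) / tau)) + rnorm(length(t), 0, 0.02)
    ev <- fit_transition_tanh(y, seq_along(y), "on", fs)
    abs(ev$transition_time - truth) / truth
  })
  expect_lt(median(errs_lo), 0.03)
})

test_that("kinetics summary computes duty ratio and frequency by definition", {
  mk_ev <- function(dir, frame) {
    structure(list(direction = dir, onset_frame = frame, transition_time = 1,
                   ok = TRUE), class = "transition_event")
  }
  # one bout frames 101 -> 301 of a 600-frame 2 Hz trace: 100 s, duty 1/3
  s <- summarize_kinetics(list(mk_ev("on", 101), mk_ev("off", 301)), 300, 2)
  expect_equal(s$bouts$duration, 100)
  expect_equal(s$duty_ratio, 1 / 3)
  # no events
  s0 <- summarize_kinetics(list(), 300, 2)
  expect_equal(s0$duty_ratio, 0)
  expect_equal(s0$transient_frequency, 0)
  # three 30 s bouts in 600 s: duty 0.15, frequency 0.3 / min
  ev3 <- list(mk_ev("on", 1), mk_ev("off", 61), mk_ev("on", 201),
              mk_ev("off", 261), mk_ev("on", 401), mk_ev("off", 461))
  s3 <- summarize_kinetics(ev3, 600, 2)
  expect_equal(s3$duty_ratio, 0.15)
  expect_equal(s3$transient_frequency, 0.3)
  # off before any on is an ordering error
  expect_error(summarize_kinetics(list(mk_ev("off", 10)), 300, 2), "OFF")
})

test_that("duty ratio of a periodic square wave equals its duty cycle", {
  sim <- generate_ava_trace(n_bouts = 4, bout_dwell = 40, inter_bout = 60,
                            noise_sd = 0, duration = 460, seed = 1)
  events <- fit_all_transitions(sim$dff, 4)
  s <- summarize_kinetics(events, 460, 4)
  expect_equal(s$duty_ratio, sim$duty_ratio, tolerance = 0.02)
})

test_that("aligned averaging reproduces noiseless events and respects CLT noise bounds", {
  fs <- 4
  t <- seq(0, 20, by = 1 / fs)
  clean <- 1 / 2 * (1 + tanh((t - 10) / 1))
  ev <- fit_transition_tanh(clean, seq_along(clean), "on", fs)
  # two identical events: mean equals the trace, sem is zero
  avg <- average_aligned_transitions(list(ev, ev), list(clean, clean), "on",
                                     fs, pre_s = 2, post_s = 2)
  expect_equal(avg$n_events, 2L)
  expect_true(all(avg$sem == 0, na.rm = TRUE))
  idx <- (ev$onset_frame - 2 * fs):(ev$onset_frame + 2 * fs)
  expect_equal(avg$mean, clean[idx], ignore_attr = TRUE)
  # one event: mean is that event
  avg1 <- average_aligned_transitions(list(ev), list(clean), "on", fs,
                                      pre_s = 2, post_s = 2)
  expect_equal(avg1$mean, clean[idx], ignore_attr = TRUE)
  # 50 noisy replicates: per-frame deviation within 3 sd / sqrt(50)
  set.seed(5)
  sigma <- 0.1
  evs <- list(); trs <- list()
  for (r in 1:50) {
    y <- clean + rnorm(length(t), 0, sigma)
    e <- fit_transition_tanh(y, seq_along(y), "on", fs)
    evs[[r]] <- e; trs[[r]] <- y
  }
  avgn <- average_aligned_transitions(evs, trs, "on", fs, pre_s = 2, post_s = 2)
  # alignment frames jitter by a frame or two, so compare against the clean
  # curve with a tolerant envelope: 3 sigma/sqrt(50) plus curve slope per frame
  slope_bound <- max(abs(diff(clean)))
  dev <- abs(avgn$mean - clean[idx])
  expect_true(all(dev <= 3 * sigma / sqrt(50) + 2 * slope_bound, na.rm = TRUE))
  expect_error(average_aligned_transitions(list(), list(), "on", fs), "usable")
})
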