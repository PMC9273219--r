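test_that("active-neuron selection ranks by standard deviation with deterministic ties", {
  set.seed(41)
  m <- rbind(rnorm(300, sd = 0.1), rnorm(300, sd = 0.5), rnorm(300, sd = 0.3))
  expect_equal(sort(select_active_neurons(m, 2)), c(2, 3))
  # identical rows tie-break to the lowest indices
  m2 <- matrix(rep(sin(1:100), 4), 4, byrow = TRUE)
  expect_equal(select_active_neurons(m2, 2), c(1L, 2L))
  expect_error(select_active_neurons(m, 1), ">= 2")
  expect_error(select_active_neurons(m, 4), "exceeds")
})

test_that("selection finds exactly the driven neurons in synthetic data", {
  sim <- generate_population(age_preset(1, seed = 2))
  d <- normalize_dff(sim$traces)
  sel <- select_active_neurons(d, 40)
  expect_setequal(sel, sim$truth$active_idx)
})

test_that("pairwise correlations match hand-enumerated oracles", {
  t <- (1:400) / 2
  s <- sin(2 * pi * 0.05 * t)
  expect_equal(pairwise_correlations(rbind(s, -s), 1:2)$r, -1)
  expect_equal(pairwise_correlations(rbind(s, s), 1:2)$r, 1)
  pc <- pairwise_correlations(four_sinusoids(), 1:4)
  expect_equal(pc$r, c(-1, 1, -1, -1, 1, -1), tolerance = 1e-12)
  expect_equal(length(pc$r), choose(4, 2))
})

test_that("zero-variance neurons yield flagged undefined pairs", {
  t <- (1:400) / 2
  s <- sin(2 * pi * 0.05 * t)
  pc <- pairwise_correlations(rbind(s, -s, rep(1, 400)), 1:3)
  expect_equal(pc$n_undefined, 2L)
  props <- correlation_proportions(pc)
  expect_equal(props$n_pairs, 1L)
  expect_equal(props$neg_prop, 1)
})

test_that("correlation proportions use strict +/-0.2 thresholds", {
  pc <- structure(list(r = c(-1, 1, -1, -1, 1, -1), n_undefined = 0L),
                  class = "pair_correlations")
  props <- correlation_proportions(pc)
  expect_equal(props$neg_prop, 4 / 6)
  expect_equal(props$pos_prop, 2 / 6)
  # boundary values fall in neither tail
  pcb <- structure(list(r = c(-0.2, 0.2, 0), n_undefined = 0L),
                   class = "pair_correlations")
  pb <- correlation_proportions(pcb)
  expect_equal(pb$neg_prop, 0)
  expect_equal(pb$pos_prop, 0)
})

test_that("independent white-noise neurons rarely exceed the thresholds", {
  set.seed(43)
  negs <- replicate(20, {
    m <- matrix(rnorm(40 * 1200), 40)
    correlation_proportions(pairwise_correlations(m, 1:40))$neg_prop
  })
  expect_lt(mean(negs), 0.01)
})

test_that("correlations are invariant to per-neuron affine rescaling", {
  set.seed(44)
  m <- matrix(rnorm(5 * 300), 5) + sin((1:300) / 10)
  a <- pairwise_correlations(m, 1:5)$r
  m2 <- sweep(sweep(m, 1, runif(5, 0.5, 4), "*"), 1, rnorm(5), "+")
  b <- pairwise_correlations(m2, 1:5)$r
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("pooled histogram is a probability distribution consistent with the proportions", {
  t <- (1:400) / 2
  pc1 <- pairwise_correlations(four_sinusoids(), 1:4)
  h1 <- pooled_correlation_histogram(list(pc1), bins = 40)
  expect_equal(sum(h1$prob), 1)
  # tail mass beyond +/-0.2 matches the proportions (thresholds on bin edges)
  props <- correlation_proportions(pc1)
  neg_bins <- which(h1$breaks[-1] <= -0.2)
  pos_bins <- which(h1$breaks[-length(h1$breaks)] >= 0.2)
  expect_equal(sum(h1$prob[neg_bins]), props$neg_prop, tolerance = 1e-12)
  expect_equal(sum(h1$prob[pos_bins]), props$pos_prop, tolerance = 1e-12)
  # all r = +1 puts all mass in the top bin
  pc2 <- structure(list(r = rep(1, 10), n_undefined = 0L),
                   class = "pair_correlations")
  h2 <- pooled_correlation_histogram(list(pc2), bins = 40)
  expect_equal(h2$prob[40], 1)
  # pooling weights sets by their pair counts
  h12 <- pooled_correlation_histogram(list(pc1, pc2), bins = 40)
  expect_equal(h12$prob[40], (2 + 10) / 16)  # the two r=+1 pairs plus pc2
  # symmetric values give a mirror-symmetric histogram
  pcs <- structure(list(r = c(-0.5, 0.5), n_undefined = 0L),
                   class = "pair_correlations")
  hs <- pooled_correlation_histogram(list(pcs), bins = 40)
  expect_equal(hs$prob, rev(hs$prob))
})

test_that("negative proportion falls monotonically with inhibition scale while positive stays put", {
  # quiescence bouts disabled: they add a common-mode component that is a
  # separate, known effect on pairwise correlations, and this test isolates
  # the inhibition mechanism
  scales <- c(1, 0.75, 0.5, 0.25, 0)
  negs <- numeric(length(scales)); poss <- numeric(length(scales))
  for (k in seq_along(scales)) {
    nv <- c(); pv <- c()
    for (seed in 1:5) {
      cfg <- population_config(inhibition_scale = scales[k], seed = seed,
                               quiescence_rate = 0)
      sim <- generate_population(cfg)
      d <- normalize_dff(sim$traces)
      sel <- select_active_neurons(d, 40)
      ddt <- tv_differentiate(d$dff[sel, ], sampling_rate = 2)
      pr <- correlation_proportions(pairwise_correlations(ddt$ddt, 1:40))
      nv <- c(nv, pr$neg_prop); pv <- c(pv, pr$pos_prop)
    }
    negs[k] <- mean(nv); poss[k] <- mean(pv)
  }
  # neg_prop tracks the inhibition scale essentially perfectly
  expect_gt(cor(scales, negs, method = "spearman"), 0.9)
  expect_true(all(diff(negs) <= 1e-3))
  # pos_prop stays within a +/-0.05 band of its full-inhibition value
  expect_true(all(abs(poss - poss[1]) <= 0.05))
})
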