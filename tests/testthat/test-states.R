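test_that("PCA recovers planted variance structure", {
  set.seed(51)
  n <- 1200
  # rank-1 data plus tiny noise: first component takes essentially everything
  latent <- sin((1:n) / 20)
  m <- outer(runif(20, 0.5, 2), latent) + matrix(rnorm(20 * n, 0, 1e-6), 20)
  traj <- run_pca(m, k = 3)
  expect_gt(traj$explained_var[1], 0.999)
  expect_equal(sum(traj$explained_var), 1, tolerance = 1e-9)
  expect_true(all(diff(traj$explained_var) <= 1e-12))
  # isotropic noise: no dominant component
  mn <- matrix(rnorm(120 * 1200), 120)
  expect_lt(run_pca(mn, k = 3)$explained_var[1], 0.05)
  expect_error(run_pca(mn, k = 200), "exceeds")
})

test_that("three orthogonal latents with 4:2:1 variances yield matching fractions", {
  set.seed(52)
  n <- 6000
  lat <- rbind(rnorm(n, sd = 2), rnorm(n, sd = sqrt(2)), rnorm(n, sd = 1))
  # orthogonal loading directions across 30 neurons
  q <- qr.Q(qr(matrix(rnorm(30 * 3), 30)))
  m <- q %*% lat
  ev <- run_pca(m, k = 3)$explained_var[1:3]
  expect_equal(ev, c(4, 2, 1) / 7, tolerance = 0.02)
})

test_that("angular changes are 0 for straight lines and 180 for reversals", {
  fs <- 2
  line <- cbind(1:100, 2 * (1:100), 0.5 * (1:100))
  a <- angular_changes(line, sampling_rate = fs, window_s = 3)
  expect_true(all(abs(a$angles) < 1e-8))
  # direction reversal every window
  w <- 6
  zig <- cbind(rep(c(seq(0, w - 1), seq(w, 1)), 10), 0, 0)
  az <- angular_changes(zig, sampling_rate = fs, window_s = w / fs)
  expect_true(any(az$angles > 179.9, na.rm = TRUE))
  expect_true(all(az$angles >= 0 & az$angles <= 180, na.rm = TRUE))
  expect_error(angular_changes(line, sampling_rate = fs, window_s = 0), "> 0")
})

test_that("random-walk increments give the isotropic sin(theta) angle law", {
  set.seed(53)
  n <- 10000
  path <- apply(matrix(rnorm(3 * (n + 1)), ncol = 3), 2, cumsum)
  a <- angular_changes(path, sampling_rate = 1, window_s = 1)
  ang <- a$angles[!is.na(a$angles)]
  expect_equal(mean(ang), 90, tolerance = 2)
  # KS distance to the sin law CDF (1 - cos(theta))/2
  emp <- stats::ecdf(ang)
  th <- seq(0, 180, by = 0.5)
  ks <- max(abs(emp(th) - (1 - cos(th * pi / 180)) / 2))
  expect_lt(ks, 0.02)
})

test_that("angles are invariant to rotation and scaling of score space", {
  set.seed(54)
  path <- apply(matrix(rnorm(3 * 500), ncol = 3), 2, cumsum)
  rot <- qr.Q(qr(matrix(rnorm(9), 3)))
  a1 <- angular_changes(path, sampling_rate = 2, window_s = 3)$angles
  a2 <- angular_changes(5 * path %*% rot, sampling_rate = 2, window_s = 3)$angles
  expect_equal(a1, a2, tolerance = 1e-8)
})

test_that("zero-displacement frames are excluded and counted", {
  path <- cbind(c(rep(0, 20), 1:30), 0, 0)
  a <- angular_changes(path, sampling_rate = 1, window_s = 2)
  expect_gt(a$n_undefined, 0)
  h <- angle_histogram(a)
  expect_equal(sum(h$prob), 1)
})

test_that("angle histograms pool trials by concatenation", {
  mk <- function(vals) structure(list(angles = vals, n_undefined = 0L),
                                 class = "angular_changes")
  h0 <- angle_histogram(mk(rep(0, 50)))
  expect_equal(h0$prob[1], 1)
  set.seed(55)
  hu <- angle_histogram(mk(runif(20000, 0, 180)), bins = 18)
  expect_true(all(abs(hu$prob - 1 / 18) < 0.01))
  # pooled two trials of n and 3n angles: second weighs 3x
  h <- angle_histogram(list(mk(rep(5, 100)), mk(rep(175, 300))), bins = 18)
  expect_equal(h$prob[1], 0.25)
  expect_equal(h$prob[18], 0.75)
})

test_that("recurrence maps are normalized, symmetric and detect exact repeats", {
  set.seed(56)
  m <- matrix(rnorm(10 * 40), 10)
  m[, 21:40] <- m[, 1:20]  # exact repeat with period 20
  rm_ <- recurrence_map(m)
  d <- rm_$dist
  expect_true(isSymmetric(d))
  expect_true(all(diag(d) == 0))
  expect_equal(max(d), 1)
  # repeated frames are exactly zero distance at lag 20
  expect_true(all(abs(d[cbind(1:20, 21:40)]) < 1e-12))
  # identical frames -> 0 entries
  expect_equal(d[1, 21], 0)
  # degenerate all-equal input flagged, all-zero map
  rm0 <- recurrence_map(matrix(1, 5, 10))
  expect_true(rm0$degenerate)
  expect_true(all(rm0$dist == 0))
})

test_that("recurrence map commutes with simultaneous frame permutation", {
  set.seed(57)
  m <- matrix(rnorm(8 * 30), 8)
  perm <- sample(30)
  d1 <- recurrence_map(m)$dist
  d2 <- recurrence_map(m[, perm])$dist
  expect_equal(d2, d1[perm, perm], tolerance = 1e-12)
})

test_that("young trajectories are directed and aged ones near-isotropic", {
  lows <- c(); firsts <- c()
  for (seed in 1:3) {
    for (day in c(1, 9)) {
      sim <- generate_population(age_preset(day, seed = seed))
      d <- normalize_dff(sim$traces)
      traj <- run_pca(d, k = 3)
      a <- angular_changes(traj, window_s = 3)
      h <- angle_histogram(a, bins = 18)
      if (day == 1) lows <- c(lows, sum(h$prob[1:3])) else
        firsts <- c(firsts, h$prob[1])
    }
  }
  # pooled young mass below 30 degrees exceeds 55%
  expect_gt(mean(lows), 0.55)
  # aged first bin within a factor 2 of the uniform 1/18
  expect_lt(mean(firsts), 2 / 18)
})
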