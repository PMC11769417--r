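test_that("acceleration norm is the per-sample Euclidean magnitude", {
  tr <- acceleration_trace(c(0, 0.02, 0.04), c(3, 0, 1), c(4, 0, 2),
                           c(0, 0, 2))
  expect_equal(acceleration_norm(tr)$a_abs, c(5, 0, 3))
})

test_that("the norm is invariant under axis permutation and sign flips", {
  set.seed(21)
  for (rep in 1:20) {
    n <- 10L
    t <- seq(0, by = 0.01, length.out = n)
    a <- matrix(rnorm(3 * n), ncol = 3)
    base <- acceleration_norm(acceleration_trace(t, a[, 1], a[, 2], a[, 3]))
    perm <- sample(3)
    signs <- sample(c(-1, 1), 3, replace = TRUE)
    b <- a[, perm] %*% diag(signs)
    alt <- acceleration_norm(acceleration_trace(t, b[, 1], b[, 2], b[, 3]))
    expect_equal(alt$a_abs, base$a_abs)
  }
})

test_that("threshold estimation: fixed default and adaptive mean + k SD", {
  ns <- norm_fixture(seq(0, 4.98, by = 0.02), rep(0.5, 250))
  expect_equal(estimate_threshold(ns), 2.0)
  expect_equal(estimate_threshold(ns, mode = "adaptive"), 0.5)

  set.seed(22)
  x <- rnorm(250, mean = 0.3, sd = 0.1)
  ns2 <- norm_fixture(seq(0, 4.98, by = 0.02), abs(x))
  o <- oracle_mean_sd(abs(x))
  expect_equal(estimate_threshold(ns2, mode = "adaptive", k = 3),
               o$mean + 3 * o$sd, tolerance = 1e-12)

  late <- norm_fixture(c(6, 7), c(0.1, 0.1))
  expect_error(estimate_threshold(late, mode = "adaptive"),
               "empty baseline")
})

test_that("impact detection by max-and-mask finds the true pulse maxima", {
  # one spike
  t <- seq(0, 10, by = 0.02)
  a <- rep(0, length(t))
  spike <- which(t >= 6)[1]
  a[spike] <- 50
  expect_equal(detect_impacts(norm_fixture(t, a), 2, n_expected = 1), spike)

  # 5 identical half-sine pulses, 8 s apart, vs per-interval brute force
  fs <- 250
  t <- (0:(50 * fs)) / fs
  a <- rep(0, length(t))
  onsets <- 6 + 8 * (0:4)
  for (t0 in onsets) {
    idx <- which(t >= t0 & t <= t0 + 0.1)
    a[idx] <- a[idx] + 80 * sin(pi * (t[idx] - t0) / 0.1)
  }
  ns <- norm_fixture(t, a)
  found <- detect_impacts(ns, 2, n_expected = 5, min_separation = 1,
                          baseline_end = 5)
  brute <- vapply(onsets, function(t0) {
    idx <- which(t >= t0 & t <= t0 + 0.1)
    idx[which.max(a[idx])]
  }, integer(1))
  expect_equal(found, brute)
})

test_that("masking suppresses close neighbours and warns on shortfall", {
  t <- seq(0, 10, by = 0.02)
  a <- rep(0, length(t))
  i1 <- which(t >= 6)[1]
  i2 <- which(t >= 6.5)[1]
  a[i1] <- 50
  a[i2] <- 80
  expect_warning(
    found <- detect_impacts(norm_fixture(t, a), 2, n_expected = 2,
                            min_separation = 1),
    "found 1")
  expect_equal(found, i2)

  flat <- norm_fixture(t, rep(0.5, length(t)))
  expect_warning(none <- detect_impacts(flat, 2, n_expected = 5),
                 "found 0")
  expect_length(none, 0L)
})

test_that("backward scan finds the first strictly sub-threshold sample", {
  ns <- norm_fixture(seq(0, 0.08, by = 0.02), c(0.5, 1.0, 4.0, 30.0, 80.0))
  seg <- segment_strike(ns, 5, threshold = 2)
  expect_equal(seg$start_index, 2L)
  expect_true(seg$valid)
  expect_equal(seg$a_abs, c(1, 4, 30, 80))

  # a sample exactly at the threshold does not terminate the scan
  ns_tie <- norm_fixture(seq(0, 0.08, by = 0.02), c(0.5, 2.0, 4.0, 30.0, 80.0))
  expect_equal(segment_strike(ns_tie, 5, threshold = 2)$start_index, 1L)

  expect_error(segment_strike(ns, 99, threshold = 2), "out of range")
})

test_that("no crossing within the lookback window flags the segment", {
  ns <- norm_fixture(seq(0, 0.98, by = 0.02), rep(5, 50))
  seg <- segment_strike(ns, 50, threshold = 2, max_lookback = 0.6)
  expect_false(seg$valid)
  expect_equal(seg$invalid_reason, "no onset crossing")
})

test_that("onset lands within one sample of the analytic threshold crossing", {
  A <- 80; T_ <- 0.1; fs <- 500; thr <- 2
  # off-grid onset: the analytic crossing bounds the detected onset sample
  t0 <- 6.0013
  t <- (0:(8 * fs)) / fs
  a <- ifelse(t >= t0 & t <= t0 + T_, A * sin(pi * (t - t0) / T_), 0)
  ns <- norm_fixture(t, a)
  pk <- detect_impacts(ns, thr, n_expected = 1, baseline_end = 5)
  seg <- segment_strike(ns, pk, thr)
  t_cross <- t0 + T_ / pi * asin(thr / A)  # a(t_cross) == thr
  expect_lt(abs(ns$time[seg$start_index] - t_cross), 1 / fs + 1e-12)
})

test_that("validity rules flag short, long and non-finite segments", {
  two <- norm_fixture(c(0, 0.02), c(1, 50))
  seg2 <- apply_validity_rules(segment_strike(two, 2, 2))
  expect_false(seg2$valid)
  expect_equal(seg2$invalid_reason, "too few samples")

  t <- seq(0, 0.2, by = 0.02)  # 11 samples, 0.2 s
  clean <- norm_fixture(c(-0.02, t) + 0.02, c(1, seq(2, 82, by = 8)))
  segc <- apply_validity_rules(segment_strike(clean, 12, 2))
  expect_true(segc$valid)

  # pulse wider than the duration bound: onset crossing exists inside the
  # lookback window but the resulting segment is 0.75 s long
  fs <- 100
  t0 <- 6; T_ <- 1.5
  t <- (0:(10 * fs)) / fs
  a <- ifelse(t >= t0 & t <= t0 + T_, 80 * sin(pi * (t - t0) / T_), 0)
  ns <- norm_fixture(t, a)
  pk <- which.max(a)
  wide <- apply_validity_rules(segment_strike(ns, pk, 2, max_lookback = 0.8),
                               max_duration = 0.6)
  expect_false(wide$valid)
  expect_equal(wide$invalid_reason, "duration out of range")

  seg_bad <- segment_strike(two, 2, 2)
  seg_bad$a_abs <- c(1, NaN, 50)
  seg_bad$time <- c(0, 0.02, 0.04)
  expect_equal(apply_validity_rules(seg_bad)$invalid_reason,
               "non-finite samples")
})

test_that("valid segments satisfy the slice invariants", {
  set.seed(23)
  for (rep in 1:25) {
    fs <- sample(c(50, 100, 250), 1)
    t0 <- 6 + runif(1)
    T_ <- runif(1, 0.05, 0.3)
    A <- runif(1, 20, 120)
    t <- (0:(9 * fs)) / fs
    a <- ifelse(t >= t0 & t <= t0 + T_, A * sin(pi * (t - t0) / T_), 0) +
      abs(rnorm(length(t), 0, 0.2))
    ns <- norm_fixture(t, a)
    pk <- suppressWarnings(detect_impacts(ns, 2, n_expected = 1,
                                          baseline_end = 5))
    if (!length(pk)) next
    seg <- segment_strike(ns, pk, 2)
    if (!seg$valid) next
    expect_lt(seg$a_abs[1], 2)
    expect_equal(max(seg$a_abs), seg$a_abs[length(seg$a_abs)])
    expect_lte(seg$start_index, seg$peak_index)
  }
})
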