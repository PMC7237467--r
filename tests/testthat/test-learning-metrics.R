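test_that("spike-triggered average is the circular mean at spike times", {
  A <- c(1, 0, 1, 0)
  expect_equal(as.numeric(spike_triggered_average(A, rep(0.7, 4))), 0.7)
  sta <- spike_triggered_average(c(1, 1), c(0, pi / 2))
  expect_equal(as.numeric(sta), pi / 4)
  # antipodal spikes: undefined circular mean
  u <- spike_triggered_average(c(1, 1), c(0, pi))
  expect_true(is.na(u) && isTRUE(attr(u, "undefined")))
  z <- spike_triggered_average(c(0, 0), c(1, 2))
  expect_true(is.na(z) && isTRUE(attr(z, "undefined")))
})

test_that("spike-triggered variance is one minus the resultant length", {
  expect_equal(spike_triggered_variance(rep(1, 6), rep(1.9, 6)), 0)
  set.seed(30)
  many <- runif(4000, 0, 2 * pi)
  expect_lt(1 - spike_triggered_variance(rep(1, 4000), many), 0.05)
  # four listed angles against hand-computed resultant
  ang <- c(0.2, 0.5, 1.0, 1.4)
  res <- sqrt(mean(sin(ang))^2 + mean(cos(ang))^2)
  expect_equal(spike_triggered_variance(rep(1, 4), ang), 1 - res)
  expect_true(spike_triggered_variance(rep(1, 4), ang) >= 0)
})

test_that("learning duration scans for permanent entry of the neighbourhood", {
  mu <- 1
  expect_equal(learning_duration(rep(1.2, 5), mu), 1L)
  r <- learning_duration(rep(1 + pi * 0.9, 5), mu)
  expect_true(is.na(r) && isTRUE(attr(r, "censored")))
  # enters, leaves, re-enters for good at index 7
  ser <- c(1, 1, 3.2, 1, 1, 3.2, 1, 1, 1, 1)
  expect_equal(learning_duration(ser, mu), 7L)
  # NA entries count as outside
  expect_equal(learning_duration(c(NA, 1, 1), mu), 2L)
})

test_that("population decoding with an equiangular frame is exact", {
  e8 <- (0:7) * pi / 4
  set.seed(31)
  for (k in 1:20) {
    v <- rnorm(2)
    vp <- population_decode(v, e8)
    expect_equal(vp, 4 * v, tolerance = 1e-12)  # tight frame, factor n/2
  }
  expect_equal(decoding_error(matrix(rnorm(40), 20, 2), e8), 0,
               tolerance = 1e-9)
  # identical axes collapse onto one line
  vp <- population_decode(c(1, 1), rep(0.6, 8))
  expect_equal(atan2(vp[2], vp[1]), 0.6, tolerance = 1e-9)
  # random axes match the direct eight-term summation
  for (k in 1:10) {
    ang <- runif(8, 0, 2 * pi); v <- rnorm(2)
    expect_equal(population_decode(v, ang), brute_decode(v, ang))
  }
  expect_error(population_decode(c(1, 0), c(NA, runif(7))), "undefined")
})

test_that("decoding error is a mean circular distance in [0, pi]", {
  # axes collapsed on 0: any stimulus decodes to the 0/pi line
  err <- decoding_error(rbind(c(0, 1)), rep(0, 8))
  expect_equal(err, pi / 2)
  set.seed(32)
  v <- matrix(rnorm(60), 30, 2)
  e <- decoding_error(v, runif(8, 0, 2 * pi))
  expect_true(e >= 0 && e <= pi)
})

test_that("the cumulative-exponential fit recovers a known rate", {
  set.seed(33)
  d <- ceiling(stats::rexp(500, rate = 0.05))
  r <- fit_learning_curve(d)
  expect_lt(abs(r - 0.05) / 0.05, 0.1)
  # degenerate all-equal data pins the rate at a boundary
  rb <- fit_learning_curve(rep(1, 10))
  expect_true(isTRUE(attr(rb, "boundary")))
  expect_error(fit_learning_curve(c(2, 3), c(FALSE, FALSE)), "at least 5")
  # censored durations are excluded
  r2 <- fit_learning_curve(c(d, rep(NA, 50)),
                           c(rep(FALSE, 500), rep(TRUE, 50)))
  expect_equal(as.numeric(r2), as.numeric(r))
})

test_that("STA recovers the receptive field of a threshold unit", {
  # unit spikes iff the stimulus is within pi/2 of its direction
  mu <- 2.2
  set.seed(34)
  phis <- runif(4000, 0, 2 * pi)
  spikes <- as.integer(circular_distance(phis, mu) < pi / 2)
  keep <- which(spikes == 1)[1:500]
  sta <- spike_triggered_average(spikes[seq_len(max(keep))],
                                 phis[seq_len(max(keep))])
  expect_lt(circular_distance(as.numeric(sta), mu), 0.1)
  stv <- spike_triggered_variance(spikes[seq_len(max(keep))],
                                  phis[seq_len(max(keep))])
  # circular variance of a uniform half-circle: 1 - 2/pi
  expect_lt(abs(stv - (1 - 2 / pi)), 0.06)
})

test_that("session-level learning metrics are coherent", {
  sess <- cached_session("thompson")
  l <- learning_metrics(sess)
  expect_true(l$frac_within_cut >= 0 && l$frac_within_cut <= 1)
  expect_true(all(l$durations[!l$censored] >= 1))
  expect_true(l$decoding_error >= 0 && l$decoding_error <= pi)
  expect_true(is.finite(l$learning_rate))
  # receptive fields are concentrated by the hundredth spike
  expect_lt(l$stv_spike100, 0.3)
})
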