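test_that("tile coding activates one tile per tiling", {
  set.seed(1)
  for (phi in runif(20, 0, 2 * pi)) {
    f <- encode_angle(phi)
    expect_length(f, 360)
    expect_equal(sum(f), 45)
    blocks <- (attr(f, "active") - 1) %/% 8
    expect_equal(as.integer(blocks), 0:44)  # exactly one per tiling
  }
  expect_identical(as.integer(encode_angle(1)),
                   as.integer(encode_angle(1 + 2 * pi)))
})

test_that("the encoding is piecewise constant with single-tiling flips", {
  delta <- 2 * pi / 360  # one breakpoint spacing
  set.seed(2)
  for (phi in runif(20, 0, 2 * pi)) {
    f1 <- encode_angle(phi)
    f2 <- encode_angle(phi + delta)
    expect_equal(sum(f1 != f2), 2)  # one tiling flips its active tile
    # within a breakpoint interval the pattern is constant
    f3 <- encode_angle(phi + delta / 10)
    changed <- sum(as.integer(f1) != as.integer(f3))
    expect_true(changed %in% c(0, 2))
  }
})

test_that("feature support is a uniform arc of width 2*pi/(n*m)", {
  f <- encode_angle(1.2)
  pf <- phi_given_features(f)
  expect_equal(pf$halfwidth, pi / 360)
  expect_equal(pf$density, 360 / (2 * pi))
  expect_equal(pf$pdf(pf$center), 360 / (2 * pi))
  expect_equal(pf$pdf(pf$center + 2 * pf$halfwidth), 0)
  # integrates to one
  grid <- seq(0, 2 * pi, length.out = 1e5 + 1)[-1]
  expect_equal(mean(pf$pdf(grid)) * 2 * pi, 1, tolerance = 1e-2)
  # the true angle lies in the support
  expect_lt(circular_distance(1.2, pf$center), pf$halfwidth)
  expect_error(phi_given_features(rep(1L, 360)), "degenerate")
})

test_that("exploration decays geometrically down to the floor", {
  expect_equal(exploration_rate(0), 1)
  expect_equal(exploration_rate(1), 0.85)
  expect_equal(exploration_rate(1e6, beta2 = 0.05), 0.05)
  eps <- exploration_rate(0:100)
  expect_true(all(diff(eps) <= 0))
})

test_that("action probabilities follow the gated soft activation", {
  q <- 0.1939
  expect_equal(action_probability(0, epsilon = 1, q = q), (1 - q) / 2)
  expect_equal(action_probability(1e12, epsilon = 0, q = q), 1 - q,
               tolerance = 1e-9)
  g <- seq(-2, 2, by = 0.05)
  p <- action_probability(g, epsilon = 0.3, q = q, gain = 5)
  expect_true(all(p >= 0 & p <= 1 - q))
  expect_true(all(diff(p) > 0))  # strictly increasing when epsilon < 1
})

test_that("observations are the noisy target-difference angle", {
  expect_error(observe(c(1, 1), c(1, 1)), "undefined")
  set.seed(3)
  o <- observe(c(10, 0), c(0, 0), beta3 = 0)
  expect_equal(o$psi, 0)
  expect_equal(o$phi, 0)
  # circular variance of the noise matches beta3
  set.seed(4)
  phis <- replicate(2e4, observe(c(0, 10), c(0, 0), beta3 = 0.04)$phi)
  dev <- atan2(sin(phis - pi / 2), cos(phis - pi / 2))
  expect_equal(var(dev), 0.04, tolerance = 0.01)
  expect_true(all(phis >= 0 & phis < 2 * pi))
})

test_that("circular distance is symmetric, wrapped and bounded", {
  expect_equal(circular_distance(0, 2 * pi), 0)
  expect_equal(circular_distance(0.1, 2 * pi - 0.1), 0.2)
  set.seed(5)
  a <- runif(100, -10, 10); b <- runif(100, -10, 10)
  expect_equal(circular_distance(a, b), circular_distance(b, a))
  expect_true(all(circular_distance(a, b) <= pi))
})
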