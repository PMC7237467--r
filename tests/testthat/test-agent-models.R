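# The four activation models: Bayesian expected utility, Thompson sampling,
# SARSA(lambda), and the perceptron.

test_that("utility is the angular reduction in target distance", {
  expect_equal(utility(1, 1.3, 1.3), pi / 2)
  expect_equal(utility(1, 0, pi), -pi / 2)
  expect_equal(utility(0, 0.3, 2.9), 0)
  expect_equal(utility(1, 0.2, 0.7), pi / 2 - 0.5)
})

test_that("belief updates add unit vectors to the resultant", {
  b <- belief_init()
  expect_equal(b$R0, 0); expect_equal(b$c, 0); expect_true(is.na(b$Phi))
  b1 <- belief_update(b, 1.1)
  expect_equal(b1$R0, 1); expect_equal(b1$Phi, 1.1); expect_equal(b1$c, 1)
  # antipodal observations cancel
  b2 <- belief_update(belief_init(), c(0.4, 0.4 + pi))
  expect_equal(b2$R0, 0, tolerance = 1e-12)
  expect_equal(b2$c, 2)
  # k identical angles give a collinear resultant of length k
  b3 <- belief_update(belief_init(), rep(2.5, 7))
  expect_equal(b3$R0, 7)
  expect_equal(b3$Phi, 2.5)
  expect_equal(b3$c, 7)
})

test_that("the belief density is a normalized von Mises family on the grid", {
  par <- agent_params("bayes")
  # uninformed belief: uniform marginal over directions
  d0 <- belief_density(belief_init(), par)
  expect_equal(sum(sweep(d0$density, 2, d0$kappa_width, "*")) * 2 * pi / 360,
               1, tolerance = 1e-9)
  expect_lt(diff(range(d0$nu_marginal)) / mean(d0$nu_marginal), 1e-9)
  # informed belief: normalized, mode of the direction marginal at Phi
  b <- belief_update(belief_init(), rep(0.9, 20) + rnorm(20, 0, 0.05))
  d <- belief_density(b, par)
  expect_equal(sum(sweep(d$density, 2, d$kappa_width, "*")) * 2 * pi / 360,
               1, tolerance = 1e-9)
  expect_lt(circular_distance(d$nu[which.max(d$nu_marginal)], b$Phi), 0.02)
})

test_that("belief recovers the true direction from noisy observations", {
  set.seed(6)
  b <- belief_update(belief_init(), (2.2 + rnorm(200, 0, 0.4)) %% (2 * pi))
  d <- belief_density(b)
  mode_nu <- d$nu[which.max(d$nu_marginal)]
  expect_lt(circular_distance(mode_nu, 2.2), 0.1)
})

test_that("uninformed Bayesian activation is zero and sharp beliefs saturate", {
  par <- agent_params("bayes")
  f <- encode_angle(1.0)
  expect_equal(bayes_activation(belief_init(), f, par), 0, tolerance = 1e-3)
  # belief concentrated at the feature centre: utility approaches pi/2
  b <- belief_update(belief_init(), rep(attr(f, "phibar"), 300))
  g <- bayes_activation(b, f, par)
  expect_gt(g, pi / 2 - 0.1)
  expect_lt(g, pi / 2 + 1e-9)
})

# 10x denser grids in every integration direction
oracle_bayes_activation <- function(belief, phibar, n = 8, m = 45,
                                    nk = 500, nnu = 3600, nphi = 160) {
  log_i0 <- function(x) ifelse(x < 50,
                               log(besselI(x, 0, expon.scaled = TRUE)) + x,
                               x - 0.5 * log(2 * pi * x))
  kg <- exp(seq(log(0.01), log(500), length.out = nk))
  mid <- (kg[-1] + kg[-nk]) / 2
  dk <- diff(c(kg[1], mid, kg[nk]))
  lw <- log(dk) + log_i0(belief$R0 * kg) - belief$c * log_i0(kg)
  w <- exp(lw - max(lw)); w <- w / sum(w)
  dnu <- 2 * pi / nnu; nu <- (seq_len(nnu) - 0.5) * dnu
  Phi <- if (is.finite(belief$Phi)) belief$Phi else 0
  prof <- numeric(nnu)
  for (g in which(w > 1e-14)) {
    k <- belief$R0 * kg[g]
    prof <- prof + w[g] * exp(k * cos(nu - Phi) - log_i0(k)) / (2 * pi)
  }
  prof <- prof / sum(prof * dnu)
  hw <- pi / (n * m)
  phis <- phibar + hw * (2 * (seq_len(nphi) - 0.5) / nphi - 1)
  util <- pi / 2 - outer(phis, nu, circular_distance)  # nphi x nnu
  sum(colMeans(util) * prof * dnu)
}

test_that("the quadrature matches a 10x denser refinement oracle", {
  par <- agent_params("bayes")
  set.seed(9)
  for (k in 1:3) {
    b <- belief_update(belief_init(),
                       (1.7 + rnorm(30, 0, runif(1, 0.2, 1.5))) %% (2 * pi))
    phibar <- attr(encode_angle(runif(1, 0, 2 * pi)), "phibar")
    g_pkg <- bayes_activation(b, phibar, par)
    g_orc <- oracle_bayes_activation(b, phibar)
    expect_equal(g_pkg, g_orc, tolerance = 1e-2)
  }
})

test_that("Thompson draws are bounded and unbiased for the expected utility", {
  par <- agent_params("thompson")
  b <- belief_update(belief_init(), (0.8 + rnorm(12, 0, 0.5)) %% (2 * pi))
  f <- encode_angle(1.1)
  set.seed(10)
  draws <- replicate(2e4, thompson_activation(b, f, par))
  expect_true(all(draws >= -pi / 2 - 1e-12 & draws <= pi / 2 + 1e-12))
  g_bayes <- bayes_activation(b, f, par)
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - g_bayes), 3 * se + 2e-3)
})

test_that("rewards are the sign of the distance change", {
  expect_equal(reward_sign(c(0, 0), c(5, 0), c(10, 0)), 1)
  expect_equal(reward_sign(c(0, 0), c(0, 0), c(10, 0)), 0)
  expect_equal(reward_sign(c(5, 0), c(0, 0), c(10, 0)), -1)
})

test_that("SARSA activation is the difference of action values", {
  par <- agent_params("rl")
  st <- rl_state(par)
  f <- encode_angle(0.5)
  expect_equal(rl_activation(st, f), 0)
  st$w[st$nm + attr(f, "active")] <- 0.2
  st$w[attr(f, "active")] <- 0.05
  expect_equal(rl_activation(st, f), 45 * (0.2 - 0.05))
})

test_that("one SARSA update matches the hand-worked arithmetic", {
  par <- agent_params("rl", n_tiles = 2, n_tilings = 2,
                      alpha = 0.1, gamma = 0.9, lambda = 0.8)
  st <- rl_state(par)
  f_t <- structure(c(1L, 0L, 1L, 0L), active = c(1L, 3L))
  f_t1 <- structure(c(0L, 1L, 0L, 1L), active = c(2L, 4L))
  # zero weights, zero reward: nothing to learn
  st0 <- sarsa_update(st, f_t, 1, 0, f_t1, 0)
  expect_equal(st0$w, rep(0, 8))
  # reward +1: replace traces on the a=1 block, TD error 1, decay 0.72
  st1 <- sarsa_update(st, f_t, 1, 1, f_t1, 0)
  expect_equal(st1$w, c(0, 0, 0, 0, 0.1, 0, 0.1, 0))
  expect_equal(st1$z, c(0, 0, 0, 0, 0.72, 0, 0.72, 0))
  # second visit: q_t = 0.2, delta = 1 - 0.2 = 0.8, w += 0.1 * 1 * 0.8
  st2 <- sarsa_update(st1, f_t, 1, 1, f_t1, 1)
  expect_equal(st2$w, c(0, 0, 0, 0, 0.18, 0, 0.18, 0))
})

test_that("replacing traces never exceed one", {
  par <- agent_params("rl")
  st <- rl_state(par)
  set.seed(12)
  for (k in 1:50) {
    f <- encode_angle(runif(1, 0, 2 * pi))
    st <- sarsa_update(st, f, rbinom(1, 1, 0.5), sample(c(-1, 0, 1), 1),
                       encode_angle(runif(1, 0, 2 * pi)), rbinom(1, 1, 0.5))
    expect_true(all(st$z >= 0 & st$z <= 1))
  }
})

test_that("SARSA orders actions on a frozen two-armed bandit", {
  # one fixed stimulus; pressing always pays +1, idling always pays -1
  par <- agent_params("rl", alpha = 0.002, gamma = 0.9, lambda = 0.8)
  st <- rl_state(par)
  f <- encode_angle(2.0)
  set.seed(13)
  a <- rbinom(301, 1, 0.5)
  for (k in 1:300)
    st <- sarsa_update(st, f, a[k], if (a[k] == 1) 1 else -1, f, a[k + 1])
  expect_gt(rl_activation(st, f), 0)
})

test_that("perceptron activation and updates follow the punitive rule", {
  par <- agent_params("ann", alpha = 0.1)
  st <- perceptron_state(par)
  f <- encode_angle(0.3)
  expect_equal(perceptron_activation(st, f), 0)
  st$b <- 1
  expect_equal(perceptron_activation(st, f), 1)
  st$b <- 0

  # T = 1 or idle: no change in either variant
  expect_identical(perceptron_update(st, f, spiked = TRUE, T = 1), st)
  expect_identical(perceptron_update(st, f, spiked = FALSE, T = 0), st)

  # feature-based punishment subtracts alpha on the active features
  st1 <- perceptron_update(st, f, spiked = TRUE, T = 0)
  expect_equal(st1$w[attr(f, "active")], rep(-0.1, 45))
  expect_equal(sum(st1$w != 0), 45)
  expect_equal(st1$b, -0.1)

  # the multiplicative rule as printed never escapes zero initialization
  stp <- perceptron_state(agent_params("ann", alpha = 0.1,
                                       perceptron_variant = "as_printed"))
  for (k in 1:10) stp <- perceptron_update(stp, f, spiked = TRUE, T = 0)
  expect_equal(stp$w, rep(0, 360))
  expect_equal(stp$b, 0)
})

test_that("a trained perceptron prefers its rewarded direction", {
  par <- agent_params("ann", alpha = 0.05)
  st <- perceptron_state(par)
  mu <- 1.0
  set.seed(14)
  for (k in 1:400) {
    phi <- runif(1, 0, 2 * pi)
    T <- as.integer(circular_distance(phi, mu) < pi / 2)
    st <- perceptron_update(st, encode_angle(phi), spiked = TRUE, T = T)
  }
  g_aligned <- perceptron_activation(st, encode_angle(mu))
  g_opposed <- perceptron_activation(st, encode_angle(mu + pi))
  expect_gt(g_aligned, g_opposed)
})
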