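test_that("success rate counts improving decision steps", {
  # distances to the target: 100, 90, 95, 80 -> improvements at steps 1 and 3
  S <- cbind(c(100, 90, 95, 80), 0)
  A <- matrix(1, 3, 2)
  expect_equal(as.numeric(success_rate(A, S, c(0, 0), delta = 0)), 2 / 3)
  expect_equal(attr(success_rate(A, S, c(0, 0)), "n"), 3)
  # idle rows leave the denominator
  A2 <- A; A2[2, ] <- 0
  expect_equal(as.numeric(success_rate(A2, S, c(0, 0))), 1)
  # no decision rows: flagged undefined
  r <- success_rate(matrix(0, 3, 2), S, c(0, 0))
  expect_true(is.na(r) && isTRUE(attr(r, "undefined")))
})

test_that("success rate agrees exactly with a brute-force loop", {
  set.seed(20)
  for (k in 1:10) {
    n <- 40
    A <- matrix(rbinom(n * 3, 1, 0.4), n, 3)
    S <- apply(matrix(rnorm((n + 1) * 2, sd = 12), n + 1, 2), 2, cumsum) + 300
    tgt <- c(280, 310)
    for (delta in c(0, 5)) {
      expect_identical(as.numeric(success_rate(A, S, tgt, delta)),
                       brute_success(A, S, tgt, delta))
    }
  }
})

test_that("success is non-increasing in the threshold and bounded by geometry", {
  sess <- cached_session("thompson")
  sw <- success_sweep(sess, deltas = seq(0, 0.05, by = 0.01))
  expect_true(all(diff(sw$success_rate) <= 0))
  # no group action can improve by more than 8 steps of 10 px (= 80 px)
  expect_equal(sw$success_rate[sw$delta_px > 80], 0)
})

test_that("pairwise success conditions on co-active steps", {
  S <- cbind(c(100, 90, 95, 80), 0)
  A <- rbind(c(1, 1), c(1, 1), c(1, 0))
  expect_equal(pairwise_success(A, S, c(0, 0), 0, 1, 2), 1 / 2)
  expect_equal(pairwise_success(A, S, c(0, 0), 0, 1, 1), 2 / 3)
  r <- pairwise_success(cbind(c(1, 1, 1), c(0, 0, 0)), S, c(0, 0), 0, 1, 2)
  expect_true(is.na(r) && isTRUE(attr(r, "undefined")))
})

test_that("correct responses use the lone-step counterfactual", {
  # target due east, far away: a step along mu improves iff |mu| < pi/2
  S <- matrix(rep(c(0, 0), 5), 5, 2, byrow = TRUE)
  A <- matrix(1, 5, 1)
  expect_equal(correct_response_rate(A, S, c(840, 0), mu_i = 0.3, i = 1), 1)
  expect_equal(correct_response_rate(A, S, c(840, 0), mu_i = pi, i = 1), 0)
  # hand example: spikes at rows 1, 3, 5 with positions on the x-axis
  S2 <- cbind(c(100, 90, 80, 70, 60), 0)
  A2 <- matrix(c(1, 0, 1, 0, 1), 5, 1)
  # mu = pi/3 points > pi/2 away from the target direction (pi): never correct
  expect_equal(correct_response_rate(A2, S2, c(0, 0), pi / 3, 1), 0)
  expect_equal(correct_response_rate(A2, S2, c(0, 0), pi, 1), 1)
  r <- correct_response_rate(matrix(0, 5, 1), S2, c(0, 0), 0, 1)
  expect_true(is.na(r) && isTRUE(attr(r, "undefined")))
})

test_that("event synchronization matches hand and brute-force oracles", {
  expect_equal(event_synchronization(c(10, 20, 30), c(10, 20, 30)), 1)
  expect_equal(event_synchronization(c(1, 2, 3), c(1000, 2000)), 0)
  # hand-evaluated: single coincidence within tau = 5 -> 1/sqrt(6)
  expect_equal(event_synchronization(c(10, 20, 30), c(12, 40)), 1 / sqrt(6))
  set.seed(21)
  for (k in 1:20) {
    ti <- sort(sample(1:120, sample(2:25, 1)))
    tj <- sort(sample(1:120, sample(2:25, 1)))
    es <- event_synchronization(ti, tj)
    expect_equal(es, brute_es(ti, tj))
    expect_equal(es, event_synchronization(tj, ti))  # symmetry
    expect_true(es >= 0 && es <= 1 + 1e-12)
  }
  expect_error(event_synchronization(numeric(0), 1), "non-empty")
})

test_that("action-time correlation is the phi coefficient", {
  set.seed(22)
  A <- cbind(a = rbinom(200, 1, 0.4))
  A <- cbind(A, b = A[, 1], c = 1 - A[, 1], d = rbinom(200, 1, 0.3))
  C <- action_time_correlation(A)
  expect_equal(C[1, 2], 1)
  expect_equal(C[1, 3], -1)
  expect_equal(C, t(C))
  # equals Spearman on binary data
  expect_equal(C, suppressWarnings(cor(A, method = "spearman")),
               tolerance = 1e-12)
  # independent columns decorrelate
  A2 <- matrix(rbinom(2e4 * 2, 1, 0.35), ncol = 2)
  expect_lt(abs(action_time_correlation(A2)[1, 2]), 0.05)
  # constant columns are flagged, not zeroed
  A3 <- cbind(rbinom(50, 1, 0.5), 1)
  expect_true(is.na(action_time_correlation(A3)[1, 2]))
})

test_that("the cooperation measure behaves like a covariance", {
  set.seed(23)
  C <- matrix(rnorm(64, 0, 0.1), 8, 8); C <- (C + t(C)) / 2; diag(C) <- 1
  S_const <- matrix(0.7, 8, 8)
  expect_equal(cooperation_measure(C, S_const), 0)
  expect_equal(cooperation_measure(C, C), var(C[upper.tri(C)]))
  expect_gte(cooperation_measure(C, C), 0)
  # anti-ordered success matrix gives negative cooperation
  expect_lt(cooperation_measure(C, -C), 0)
  # adding a constant to all success entries changes nothing
  expect_equal(cooperation_measure(C, C + 0.3), cooperation_measure(C, C))
  Sna <- C; Sna[1, 2] <- Sna[2, 1] <- NA
  expect_error(cooperation_measure(C, Sna), "undefined pair")
})

test_that("synchronization profiles bucket pairs by angular distance", {
  mu <- (0:7) * pi / 4
  ES1 <- matrix(0.5, 8, 8); diag(ES1) <- 1
  p1 <- synchronization_by_distance(ES1, mu)
  expect_equal(p1$mean_es, rep(0.5, 4))
  # constructed monotone synchronization decays with distance
  D <- outer(mu, mu, circular_distance)
  p2 <- synchronization_by_distance(1 - D / pi, mu)
  expect_true(all(diff(p2$mean_es) < 0))
  expect_equal(p2$distance, c(pi / 4, pi / 2, 3 * pi / 4, pi))
})

test_that("simulated cooperative groups show synergy and a U-shaped profile", {
  sess <- cached_session("thompson")
  m <- group_metrics(sess)
  expect_gt(m$synergy, 0)  # group success exceeds mean individual correctness
  expect_true(all(m$event_sync >= 0 & m$event_sync <= 1 + 1e-12, na.rm = TRUE))
  expect_equal(m$event_sync, t(m$event_sync))
  prof <- m$es_profile
  expect_gt(prof$mean_es[prof$distance == pi / 4],
            prof$mean_es[prof$distance == pi])
  expect_gt(m$zeta, 0)
})
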