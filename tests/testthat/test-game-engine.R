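test_that("trial geometry honours the fixed distance and the screen brim", {
  cfg <- game_config()
  set.seed(1)
  for (k in 1:200) {
    g <- sample_trial_geometry(cfg)
    expect_equal(sqrt(sum((g$start - g$target)^2)), 840)
    expect_true(all(g$start >= c(198, 108)) && all(g$start <= c(1782, 972)))
    expect_true(all(g$target >= c(198, 108)) && all(g$target <= c(1782, 972)))
  }
  set.seed(7); a <- sample_trial_geometry(cfg)
  set.seed(7); b <- sample_trial_geometry(cfg)
  expect_identical(a, b)
})

test_that("infeasible geometry aborts instead of spinning", {
  cfg <- game_config()
  cfg$brim_fraction <- 0.49
  cfg$target_distance <- 840   # far wider than the remaining 2% window
  class(cfg) <- "ng_config"
  set.seed(1)
  expect_error(sample_trial_geometry(cfg), "did not terminate")
})

test_that("direction assignments are an equiangular rotated wind rose", {
  set.seed(2)
  mu <- assign_directions(8)
  gaps <- diff(sort(mu))
  expect_equal(gaps, rep(pi / 4, 7), tolerance = 1e-12)
  set.seed(5); a <- assign_directions(8)
  set.seed(5); b <- assign_directions(8)
  expect_identical(a, b)
  # the rotation offset is uniform on [0, pi/4)
  set.seed(3)
  offs <- replicate(1e4, min(assign_directions(8)))
  ks <- suppressWarnings(stats::ks.test(offs / (pi / 4), "punif"))
  expect_gt(ks$p.value, 0.001)
})

test_that("cursor steps are vector sums of active players' unit steps", {
  mu <- (0:7) * pi / 4
  s <- c(500, 500)
  expect_equal(step_cursor(s, rep(0, 8), mu), s)
  # antipodal pair cancels
  expect_equal(step_cursor(s, c(1, 0, 0, 0, 1, 0, 0, 0), mu), s)
  # single active player moves 10 px along its direction
  s1 <- step_cursor(s, c(0, 1, 0, 0, 0, 0, 0, 0), mu)
  expect_equal(sqrt(sum((s1 - s)^2)), 10)
  expect_equal(atan2(s1[2] - s[2], s1[1] - s[1]), pi / 4)
  # additivity over disjoint activation patterns
  set.seed(4)
  for (k in 1:20) {
    u <- rbinom(8, 1, 0.5); v <- rbinom(8, 1, 0.5) * (1 - u)
    expect_equal(step_cursor(s, u + v, mu),
                 step_cursor(s, u, mu) + step_cursor(s, v, mu) - s)
  }
})

test_that("omniscient scripted agents always reach the target quickly", {
  set.seed(11)
  b <- run_batch("scripted", game_config(trials_per_batch = 10))
  expect_true(all(b$trials$reached == 1))
  # ceil(840/10) productive steps plus margin for the diagonal geometry
  expect_true(all(b$trials$steps <= 84 + 60))
  expect_equal(nrow(b$trials), 10)
})

test_that("identical seeds give bit-identical batches", {
  cfg <- game_config(trials_per_batch = 3)
  par <- agent_params("thompson")
  set.seed(42); a <- run_batch("thompson", cfg, par)
  set.seed(42); b <- run_batch("thompson", cfg, par)
  expect_identical(a$actions, b$actions)
  expect_identical(a$pos, b$pos)
  expect_identical(a$trials, b$trials)
})

test_that("frozen learning (beta1 -> 0) leaves beliefs at initialization", {
  cfg <- game_config(trials_per_batch = 2)
  par <- agent_params("thompson", beta1 = 1e-12)
  set.seed(8)
  b <- run_batch("thompson", cfg, par)
  for (u in b$units) {
    expect_equal(u$c, 0)
    expect_equal(u$R0, 0)
  }
  expect_true(all(b$spikes > 0))  # units still act, they just never update
})

test_that("recorded trajectories are self-consistent", {
  b <- cached_session("thompson")$batches[[1]]
  # within a trial, the position after step t is the position before t+1
  same_trial <- b$trial[-1] == b$trial[-length(b$trial)]
  expect_equal(b$pos_next[which(same_trial), ],
               b$pos[which(same_trial) + 1, ])
  expect_equal(colSums(b$actions), as.numeric(b$spikes))
})
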