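#' Generate a synthetic human-style event log
#'
#' Emulates the recording format of the original experiment (per-player
#' millisecond press times plus a sampled cursor trajectory) with simple
#' direction-tuned point processes: player `i` presses in a time step with
#' probability `base_rate * dt` when the current target-difference angle is
#' within `tuning_width` of the player's direction `mu_i`, and at a tenth of
#' that rate otherwise.  Press timestamps are jittered uniformly by up to
#' `jitter_ms` (strictly less than half a step, so per-player press order is
#' preserved); trajectory samples stay on the step grid.  Tuned players
#' exercise every analysis path: they produce a U-shaped synchronization
#' profile and a positive cooperation measure, while `tuning_width = pi`
#' (untuned) yields the independent-actor null.
#'
#' This generator is a synthetic stand-in for the undeposited human
#' recordings; it is not a behavioural model.
#'
#' @param tuning_width Angular half-width of each player's response field,
#'   radians, in `(0, pi]`.
#' @param base_rate In-field press rate, spikes per second.
#' @param jitter_ms Timestamp jitter amplitude (must be `< dt_ms / 2`).
#' @param trials Number of trials (one batch).
#' @param mu Direction assignment; drawn if missing.
#' @param config Game configuration (uses geometry and `dt_ms`).
#' @return An `ng_event_log` with batch and trial records, ready for
#'   [discretize_time()] / [session_from_log()].
#' @export
generate_fixture <- function(tuning_width = pi / 2, base_rate = 3,
                             jitter_ms = 20, trials = 10, mu = NULL,
                             config = game_config()) {
  stopifnot(tuning_width > 0, tuning_width <= pi, base_rate > 0,
            jitter_ms >= 0, jitter_ms < config$dt_ms / 2, trials >= 1)
  np <- config$n_players
  if (is.null(mu)) mu <- assign_directions(np)
  dt <- config$dt_ms
  p_hi <- min(0.95, base_rate * dt / 1000)
  p_lo <- p_hi / 10

  presses <- list(); traj <- list(); trl <- list()
  g <- 0
  for (trial in seq_len(trials)) {
    geom <- sample_trial_geometry(config)
    s <- geom$start; tgt <- geom$target
    trl[[trial]] <- data.frame(t_ms = g * dt, batch = 1, trial = trial,
                               start_x = s[1], start_y = s[2],
                               target_x = tgt[1], target_y = tgt[2])
    nstep <- 0
    while (sqrt(sum((tgt - s)^2)) > config$target_radius &&
           nstep < config$max_steps_per_trial) {
      psi <- .wrap2pi(atan2(tgt[2] - s[2], tgt[1] - s[1]))
      p <- ifelse(circular_distance(psi, mu) < tuning_width, p_hi, p_lo)
      a <- runif(np) < p
      traj[[length(traj) + 1]] <- data.frame(t_ms = g * dt, x = s[1],
                                             y = s[2])
      if (any(a)) {
        jit <- runif(sum(a), -jitter_ms, jitter_ms)
        presses[[length(presses) + 1]] <-
          data.frame(player = which(a), t_ms = g * dt + jit)
        s <- s + config$step_length * c(sum(cos(mu[a])), sum(sin(mu[a])))
      }
      g <- g + 1
      nstep <- nstep + 1
    }
  }
  traj[[length(traj) + 1]] <- data.frame(t_ms = g * dt, x = s[1], y = s[2])
  presses <- do.call(rbind, presses)
  presses <- presses[order(presses$t_ms, presses$player), ]
  rownames(presses) <- NULL
  batches <- data.frame(t_ms = 0, batch = 1,
                        matrix(mu, nrow = 1,
                               dimnames = list(NULL,
                                 paste0("mu.", seq_len(np)))))
  structure(list(presses = presses, trajectory = do.call(rbind, traj),
                 batches = batches, trials = do.call(rbind, trl)),
            class = "ng_event_log", dt_ms = dt)
}
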