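#' Sample start and target positions for one trial
#'
#' Draws a start position uniformly over the screen and a target at the fixed
#' trial distance along a uniformly drawn angle; both points must lie outside
#' the rejection brim at the screen edges, otherwise the pair is redrawn.
#'
#' @param config An [game_config()] object.
#' @return A list with numeric `start` and `target` (x, y in pixels).
#' @examples
#' set.seed(1)
#' g <- sample_trial_geometry(game_config())
#' sqrt(sum((g$start - g$target)^2))  # always the configured distance
#' @export
sample_trial_geometry <- function(config = game_config()) {
  v <- .ng_sample_geometry(config$screen_width, config$screen_height,
                           config$target_distance, config$brim_fraction)
  list(start = v[1:2], target = v[3:4])
}

#' Assign hidden movement directions
#'
#' Draws one uniform rotation of an equiangular wind rose of
#' `n_players` directions and randomly permutes the rotated directions over
#' the players.  Pairwise circular gaps are therefore exact multiples of
#' `2*pi/n_players`.
#'
#' @param n_players Number of decision units.
#' @return Numeric vector of per-player direction angles in `[0, 2*pi)`.
#' @export
assign_directions <- function(n_players = 8) {
  sector <- 2 * pi / n_players
  omega <- runif(1, 0, sector)
  dirs <- (omega + sector * (seq_len(n_players) - 1)) %% (2 * pi)
  sample(dirs)
}

#' Advance the cursor by one group decision
#'
#' The group displacement is the vector sum of the active players' unit
#' steps: `s' = s + sum_i a_i * step_length * (cos mu_i, sin mu_i)`.
#'
#' @param cursor Numeric length-2 cursor position.
#' @param actions Binary vector, one entry per player.
#' @param mu Per-player direction angles.
#' @param step_length Step length in pixels.
#' @return The new cursor position.
#' @export
step_cursor <- function(cursor, actions, mu, step_length = 10) {
  stopifnot(length(actions) == length(mu), all(actions %in% c(0, 1)))
  a <- as.numeric(actions)
  cursor + step_length * c(sum(a * cos(mu)), sum(a * sin(mu)))
}

#' Run one batch of trials
#'
#' Plays `config$trials_per_batch` trials with a fresh set of decision units
#' sharing one hidden direction assignment.  Unit learning state persists
#' across trials within the batch and is reset between batches (each call
#' starts from scratch).
#'
#' @param model Model name (`"bayes"`, `"thompson"`, `"rl"`, `"ann"`, or the
#'   noise-free omniscient `"scripted"` reference agent).
#' @param config [game_config()].
#' @param params [agent_params()]; defaults to the model's defaults.
#' @param mu Direction assignment; drawn with [assign_directions()] if
#'   missing.
#' @return An `ng_batch` object: binary action matrix `actions` (steps x
#'   players), cursor positions before (`pos`) and after (`pos_next`) each
#'   step, per-step trial index, a `trials` data frame (start, target, steps,
#'   reached), final per-unit learning state, and per-unit spike counts.
#' @export
run_batch <- function(model, config = game_config(), params = NULL,
                      mu = NULL) {
  if (inherits(model, "ng_params")) {
    params <- model
    model <- params$model
  }
  if (is.null(params)) params <- agent_params(model)
  stopifnot(identical(params$model, model))
  if (is.null(mu)) mu <- assign_directions(config$n_players)
  stopifnot(length(mu) == config$n_players)
  out <- .ng_run_batch(.model_id(model), unclass(config), unclass(params), mu)
  out$mu <- mu
  out$model <- model
  structure(out, class = "ng_batch")
}

#' Run a full session
#'
#' A session is `config$n_batches` batches; directions are redrawn and units
#' are reset at each batch boundary.
#'
#' @inheritParams run_batch
#' @param seed Optional integer seed applied with [set.seed()] before the
#'   first batch; identical seeds give bit-identical sessions.
#' @param progress Print a one-line progress note every 10 batches.
#' @return An `ng_session` object (list of `ng_batch` plus config/params).
#' @examples
#' sess <- run_session("thompson", game_config(n_batches = 2), seed = 1)
#' summary(sess)
#' @export
run_session <- function(model, config = game_config(), params = NULL,
                        seed = NULL, progress = FALSE) {
  if (inherits(model, "ng_params")) {
    params <- model
    model <- params$model
  }
  if (is.null(params)) params <- agent_params(model)
  if (!is.null(seed)) set.seed(seed)
  batches <- vector("list", config$n_batches)
  for (b in seq_len(config$n_batches)) {
    batches[[b]] <- run_batch(model, config, params)
    if (progress && b %% 10 == 0)
      message(sprintf("  batch %d/%d", b, config$n_batches))
  }
  structure(list(model = model, config = config, params = params,
                 seed = seed, batches = batches),
            class = "ng_session")
}

#' @export
print.ng_session <- function(x, ...) {
  n_steps <- sum(vapply(x$batches, function(b) nrow(b$actions), 0L))
  cat(sprintf("Simulated session: %s model, %d batches x %d trials, %d decision steps\n",
              x$model, length(x$batches), x$config$trials_per_batch, n_steps))
  invisible(x)
}

#' @export
summary.ng_session <- function(object, delta = 0, ...) {
  m <- group_metrics(object, delta = delta, es = FALSE)
  reached <- unlist(lapply(object$batches, function(b) b$trials$reached))
  steps <- unlist(lapply(object$batches, function(b) b$trials$steps))
  out <- list(model = object$model,
              n_batches = length(object$batches),
              trials_reached = mean(reached),
              median_trial_steps = stats::median(steps),
              success_rate = m$success_rate,
              mean_correct_response = m$mean_correct_response)
  class(out) <- "summary.ng_session"
  out
}

#' @export
print.summary.ng_session <- function(x, ...) {
  cat(sprintf("%s model: %d batches, %.0f%% trials reached the target (median %g steps)\n",
              x$model, x$n_batches, 100 * x$trials_reached,
              x$median_trial_steps))
  cat(sprintf("  group success rate        : %.1f%%\n", 100 * x$success_rate))
  cat(sprintf("  mean correct-response rate: %.1f%%\n",
              100 * x$mean_correct_response))
  invisible(x)
}

# per-row target coordinates of a batch
.batch_targets <- function(batch) {
  tr <- batch$trials
  cbind(tr$target_x[batch$trial], tr$target_y[batch$trial])
}

# distances to the current target before and after each step
.batch_distances <- function(batch) {
  tg <- .batch_targets(batch)
  d0 <- sqrt((tg[, 1] - batch$pos[, 1])^2 + (tg[, 2] - batch$pos[, 2])^2)
  d1 <- sqrt((tg[, 1] - batch$pos_next[, 1])^2 +
             (tg[, 2] - batch$pos_next[, 2])^2)
  cbind(d0, d1)
}
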