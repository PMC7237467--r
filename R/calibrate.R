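#' Grid-search calibration of unit hyperparameters
#'
#' The original study fitted the unit hyperparameters so that each model's
#' group performance matched the human groups; those fitted values are not
#' published.  This harness recovers workable values: it runs scaled-down
#' sessions over a coarse grid of hyperparameter candidates and scores each
#' candidate by its distance to target group statistics (success rate,
#' optionally the mean correct-response rate).
#'
#' @param model Model name.
#' @param grid Data frame of candidate overrides; columns must be
#'   [agent_params()] argument names.
#' @param target_success Target group success rate (fraction).
#' @param target_correct Optional target mean correct-response rate.
#' @param config Session shape used for scoring (default: 8 batches).
#' @param seeds Seeds averaged per candidate.
#' @param verbose Print one line per candidate.
#' @return The `grid` with appended `success`, `correct`, `score` columns,
#'   sorted by score (best first), with the best row as attribute `best`.
#' @export
calibrate_model <- function(model, grid, target_success,
                            target_correct = NULL,
                            config = game_config(n_batches = 8),
                            seeds = 1:2, verbose = FALSE) {
  stopifnot(is.data.frame(grid), nrow(grid) >= 1)
  res <- grid
  res$success <- NA_real_
  res$correct <- NA_real_
  for (k in seq_len(nrow(grid))) {
    overrides <- as.list(grid[k, , drop = FALSE])
    par <- do.call(agent_params, c(list(model = model), overrides))
    succ <- corr <- numeric(length(seeds))
    for (s in seq_along(seeds)) {
      sess <- run_session(model, config, par, seed = seeds[s])
      m <- group_metrics(sess, es = FALSE)
      succ[s] <- m$success_rate
      corr[s] <- m$mean_correct_response
    }
    res$success[k] <- mean(succ)
    res$correct[k] <- mean(corr)
    if (verbose)
      message(sprintf("  [%d/%d] %s -> success %.3f correct %.3f",
                      k, nrow(grid),
                      paste(names(grid), unlist(overrides), sep = "=",
                            collapse = " "),
                      res$success[k], res$correct[k]))
  }
  res$score <- abs(res$success - target_success)
  if (!is.null(target_correct))
    res$score <- res$score + abs(res$correct - target_correct)
  res <- res[order(res$score), ]
  attr(res, "best") <- res[1, ]
  res
}

#' Write a calibration profile
#'
#' Stores per-model hyperparameter overrides as YAML, the format consumed
#' by [calibrated_params()].
#'
#' @param profiles Named list (per model) of named override lists.
#' @param path Output YAML file.
#' @export
write_calibration <- function(profiles, path) {
  yaml::write_yaml(profiles, path)
  invisible(path)
}
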