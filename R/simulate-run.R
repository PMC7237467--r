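# Run orchestration: simulate to disk, analyze run directories, summarize
# several runs.  These functions (plus generate_fixture and calibrate_model)
# are the package's command surface; inst/cli/neurongame.R wraps them for
# shell use.

#' Simulate a session and write it to disk
#'
#' Runs a full session and writes the continuous event log (JSON-Lines),
#' one action-matrix CSV per batch, the configuration YAML, and a manifest.
#'
#' @param model Model name.
#' @param config [game_config()].
#' @param params [agent_params()]; defaults to [calibrated_params()] when a
#'   calibration profile is available, else to model defaults.
#' @param seed Integer seed.
#' @param out_dir Output directory (created if needed).
#' @return The manifest (also written as `manifest.json`), invisibly.
#' @export
simulate_run <- function(model, config = game_config(), params = NULL,
                         seed = 1, out_dir) {
  if (is.null(params)) {
    params <- tryCatch(calibrated_params(model),
                       error = function(e) agent_params(model))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sess <- run_session(model, config, params, seed = seed)
  log <- event_log(sess)
  write_event_log(log, file.path(out_dir, "eventlog.jsonl"))
  write_game_config(config, file.path(out_dir, "config.yaml"))
  batch_files <- character(length(sess$batches))
  for (b in seq_along(sess$batches)) {
    batch <- sess$batches[[b]]
    batch_files[b] <- sprintf("actions_b%03d.csv", b)
    write_action_matrix(batch$actions, batch$pos, .batch_targets(batch),
                        file.path(out_dir, batch_files[b]))
  }
  manifest <- list(package_version = as.character(utils::packageVersion("neurongame")),
                   model = model, seed = seed,
                   config = unclass(config),
                   params = unclass(params)[setdiff(names(params), "as_printed")],
                   files = c("eventlog.jsonl", "config.yaml", batch_files))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Analyze a stored run directory
#'
#' Re-runs the session named by the run's manifest (exact reproduction via
#' the stored seed and configuration) and writes the cooperation or
#' learning report as JSON plus CSV side tables.
#'
#' @param run_dir Directory written by [simulate_run()].
#' @param delta Success threshold in pixels.
#' @param out Output JSON path (default inside `run_dir`).
#' @return The metrics object, invisibly.
#' @export
analyze_group <- function(run_dir, delta = 0,
                          out = file.path(run_dir, "metrics.json")) {
  sess <- .rerun_manifest(run_dir)
  m <- group_metrics(sess, delta = delta)
  rep <- list(model = m$model, delta = delta,
              success_rate = m$success_rate,
              correct_response = m$correct_response,
              mean_correct_response = m$mean_correct_response,
              synergy = m$synergy, zeta = m$zeta,
              correlation = m$correlation,
              pairwise_success = m$pairwise_success,
              event_sync = m$event_sync)
  jsonlite::write_json(rep, out, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  utils::write.csv(success_sweep(sess),
                   file.path(dirname(out), "delta_sweep.csv"),
                   row.names = FALSE)
  invisible(m)
}

#' @rdname analyze_group
#' @export
analyze_learning <- function(run_dir,
                             out = file.path(run_dir, "learning.json")) {
  sess <- .rerun_manifest(run_dir)
  l <- learning_metrics(sess)
  rep <- list(model = l$model,
              frac_within_cut = l$frac_within_cut,
              duration_cut = l$duration_cut,
              learning_rate = l$learning_rate,
              decoding_error = l$decoding_error,
              durations = l$durations, censored = l$censored)
  jsonlite::write_json(rep, out, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(l)
}

.rerun_manifest <- function(run_dir) {
  man <- jsonlite::read_json(file.path(run_dir, "manifest.json"),
                             simplifyVector = TRUE)
  config <- do.call(game_config, man$config)
  params <- do.call(agent_params, man$params[setdiff(names(man$params),
                                                     c("model"))] |>
                      c(list(model = man$model)))
  run_session(man$model, config, params, seed = man$seed)
}

#' Summarize several runs into one table
#'
#' One row per run: model, seed, group success rate, mean correct-response
#' rate, cooperation measure, fitted learning rate and decoding error -- the
#' coordinates of the learning-rate versus success-rate summary plane.
#'
#' @param ... Run directories written by [simulate_run()].
#' @param out Optional CSV path.
#' @return Data frame, one row per run.
#' @export
report_runs <- function(..., out = NULL) {
  dirs <- c(...)
  rows <- lapply(dirs, function(d) {
    man <- jsonlite::read_json(file.path(d, "manifest.json"),
                               simplifyVector = TRUE)
    sess <- .rerun_manifest(d)
    m <- group_metrics(sess, es = FALSE)
    l <- learning_metrics(sess)
    data.frame(run = d, model = man$model, seed = man$seed,
               success_rate = m$success_rate,
               mean_correct_response = m$mean_correct_response,
               zeta = m$zeta, learning_rate = l$learning_rate,
               decoding_error = l$decoding_error)
  })
  df <- do.call(rbind, rows)
  if (!is.null(out)) utils::write.csv(df, out, row.names = FALSE)
  df
}
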