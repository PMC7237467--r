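# Event-log construction and file formats (JSON-Lines logs, CSV matrices,
# YAML configs).

#' Build a continuous-time event log from a session
#'
#' Synthesizes millisecond timestamps for a simulated session in the format
#' of the original recordings: per-player button-press times plus sampled
#' cursor positions, with batch and trial marker records.  Each decision
#' step lasts `config$dt_ms`; the clock runs continuously across trials and
#' batches.
#'
#' @param session An `ng_session`.
#' @return An `ng_event_log`: data frames `presses` (player, t_ms),
#'   `trajectory` (t_ms, x, y), `batches` (t_ms, batch, mu.1..), `trials`
#'   (t_ms, batch, trial, start/target coordinates), with the step duration
#'   in `attr(, "dt_ms")`.
#' @export
event_log <- function(session) {
  stopifnot(inherits(session, "ng_session"))
  dt <- session$config$dt_ms
  np <- session$config$n_players
  presses <- list(); traj <- list(); batches <- list(); trials <- list()
  g <- 0  # global step counter
  for (b in seq_along(session$batches)) {
    batch <- session$batches[[b]]
    N <- nrow(batch$actions)
    t_ms <- (g + seq_len(N) - 1) * dt
    batches[[b]] <- data.frame(t_ms = g * dt, batch = b,
                               matrix(batch$mu, nrow = 1,
                                      dimnames = list(NULL,
                                        paste0("mu.", seq_len(np)))))
    tr <- batch$trials
    first_step <- c(0, cumsum(tr$steps))[seq_len(nrow(tr))]
    trials[[b]] <- data.frame(
      t_ms = (g + first_step) * dt, batch = b, trial = seq_len(nrow(tr)),
      start_x = tr$start_x, start_y = tr$start_y,
      target_x = tr$target_x, target_y = tr$target_y)
    idx <- which(batch$actions == 1, arr.ind = TRUE)
    presses[[b]] <- data.frame(player = idx[, 2], t_ms = t_ms[idx[, 1]])
    traj[[b]] <- data.frame(t_ms = t_ms, x = batch$pos[, 1],
                            y = batch$pos[, 2])
    g <- g + N
  }
  # one final position after the session's last step; earlier trial and
  # batch teleports appear as jumps between consecutive samples
  last <- session$batches[[length(session$batches)]]
  traj[[length(traj) + 1]] <-
    data.frame(t_ms = g * dt, x = last$pos_next[nrow(last$pos_next), 1],
               y = last$pos_next[nrow(last$pos_next), 2])
  presses <- do.call(rbind, presses)
  presses <- presses[order(presses$t_ms, presses$player), ]
  rownames(presses) <- NULL
  structure(list(presses = presses,
                 trajectory = do.call(rbind, traj),
                 batches = do.call(rbind, batches),
                 trials = do.call(rbind, trials)),
            class = "ng_event_log", dt_ms = dt)
}

#' @export
print.ng_event_log <- function(x, ...) {
  cat(sprintf("Event log: %d presses, %d trajectory samples, %d batches, %d trials\n",
              nrow(x$presses), nrow(x$trajectory), nrow(x$batches),
              nrow(x$trials)))
  invisible(x)
}

#' Write / read an event log as JSON-Lines
#'
#' One JSON record per line: `{"kind":"press","player":i,"t_ms":t}`,
#' `{"kind":"pos","t_ms":t,"x":x,"y":y}`, `{"kind":"batch","t_ms":t,"mu":[...]}`,
#' `{"kind":"trial","t_ms":t,"start":[x,y],"target":[x,y]}`.
#'
#' @param log An `ng_event_log`.
#' @param path Output file.
#' @return `path`, invisibly (`write_event_log`); an `ng_event_log`
#'   (`read_event_log`).
#' @export
write_event_log <- function(log, path) {
  stopifnot(inherits(log, "ng_event_log"))
  con <- file(path, "w")
  on.exit(close(con))
  emit <- function(x) writeLines(jsonlite::toJSON(x, auto_unbox = TRUE,
                                                  digits = NA), con)
  np <- sum(startsWith(names(log$batches), "mu."))
  for (b in seq_len(nrow(log$batches))) {
    row <- log$batches[b, ]
    emit(list(kind = "batch", t_ms = row$t_ms,
              mu = as.numeric(row[paste0("mu.", seq_len(np))])))
    tr <- log$trials[log$trials$batch == row$batch, ]
    for (k in seq_len(nrow(tr)))
      emit(list(kind = "trial", t_ms = tr$t_ms[k],
                start = c(tr$start_x[k], tr$start_y[k]),
                target = c(tr$target_x[k], tr$target_y[k])))
  }
  # stream presses and positions in time order
  ev <- rbind(
    data.frame(kind = "press", t_ms = log$presses$t_ms,
               player = log$presses$player, x = NA_real_, y = NA_real_),
    data.frame(kind = "pos", t_ms = log$trajectory$t_ms, player = NA_integer_,
               x = log$trajectory$x, y = log$trajectory$y))
  ev <- ev[order(ev$t_ms, ev$kind != "pos"), ]
  for (k in seq_len(nrow(ev))) {
    if (ev$kind[k] == "press")
      emit(list(kind = "press", player = ev$player[k], t_ms = ev$t_ms[k]))
    else
      emit(list(kind = "pos", t_ms = ev$t_ms[k], x = ev$x[k], y = ev$y[k]))
  }
  invisible(path)
}

#' @rdname write_event_log
#' @param dt_ms Step duration recorded in the returned log attribute (used
#'   by round-trip consumers; detected from the trajectory if `NULL`).
#' @export
read_event_log <- function(path, dt_ms = NULL) {
  lines <- readLines(path)
  recs <- lapply(lines, jsonlite::fromJSON)
  kinds <- vapply(recs, `[[`, "", "kind")
  pr <- recs[kinds == "press"]
  po <- recs[kinds == "pos"]
  ba <- recs[kinds == "batch"]
  tr <- recs[kinds == "trial"]
  presses <- data.frame(
    player = vapply(pr, function(r) as.integer(r$player), 0L),
    t_ms = vapply(pr, function(r) as.numeric(r$t_ms), 0))
  trajectory <- data.frame(
    t_ms = vapply(po, function(r) as.numeric(r$t_ms), 0),
    x = vapply(po, function(r) as.numeric(r$x), 0),
    y = vapply(po, function(r) as.numeric(r$y), 0))
  batches <- NULL
  if (length(ba)) {
    mus <- do.call(rbind, lapply(ba, function(r) as.numeric(r$mu)))
    colnames(mus) <- paste0("mu.", seq_len(ncol(mus)))
    batches <- data.frame(t_ms = vapply(ba, function(r) as.numeric(r$t_ms), 0),
                          batch = seq_along(ba), mus)
  }
  trials <- NULL
  if (length(tr)) {
    trials <- data.frame(
      t_ms = vapply(tr, function(r) as.numeric(r$t_ms), 0),
      start_x = vapply(tr, function(r) as.numeric(r$start[1]), 0),
      start_y = vapply(tr, function(r) as.numeric(r$start[2]), 0),
      target_x = vapply(tr, function(r) as.numeric(r$target[1]), 0),
      target_y = vapply(tr, function(r) as.numeric(r$target[2]), 0))
    if (!is.null(batches)) {
      trials$batch <- findInterval(trials$t_ms, batches$t_ms)
      trials$trial <- stats::ave(trials$t_ms, trials$batch,
                                 FUN = seq_along)
    }
  }
  structure(list(presses = presses, trajectory = trajectory,
                 batches = batches, trials = trials),
            class = "ng_event_log", dt_ms = dt_ms)
}

#' Write / read an action matrix with its trajectory as CSV
#'
#' Header `t,a1..aP,x,y,tx,ty`: discrete time index, binary actions, cursor
#' position before the step, and the current target.
#'
#' @param A Binary action matrix.
#' @param S Cursor positions, one row per action row.
#' @param target Per-row target matrix (or a single target recycled).
#' @param path Output file.
#' @export
write_action_matrix <- function(A, S, target, path) {
  np <- ncol(A)
  if (is.null(dim(target))) target <- matrix(target, nrow(A), 2, byrow = TRUE)
  df <- data.frame(t = seq_len(nrow(A)), A, S[seq_len(nrow(A)), , drop = FALSE],
                   target)
  names(df) <- c("t", paste0("a", seq_len(np)), "x", "y", "tx", "ty")
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_action_matrix
#' @export
read_action_matrix <- function(path) {
  df <- read.csv(path)
  acols <- grep("^a[0-9]+$", names(df))
  list(A = as.matrix(df[acols]), S = as.matrix(df[c("x", "y")]),
       target = as.matrix(df[c("tx", "ty")]), t = df$t)
}

#' Write / read a game configuration as YAML
#'
#' @param config An [game_config()] object.
#' @param path File path.
#' @export
write_game_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_game_config
#' @export
read_game_config <- function(path) {
  do.call(game_config, yaml::read_yaml(path))
}
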