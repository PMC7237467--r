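#' Discretize a continuous-time event log
#'
#' Bins millisecond press logs into a binary action matrix.  The bin width
#' is the minimum over players of each player's minimum inter-press
#' interval: the largest width that provably guarantees that no player
#' appears more than once in any bin.  Events in the same bin count as
#' simultaneous; the trajectory is resampled at the bin boundaries (last
#' observed position at or before each boundary).
#'
#' @param log An `ng_event_log` (from [event_log()], [read_event_log()] or
#'   [generate_fixture()]).
#' @return List with the binary `A` (bins x players), the resampled
#'   trajectory `S` (`nrow(A) + 1` rows), and `bin_width_ms`.
#' @export
discretize_time <- function(log) {
  stopifnot(inherits(log, "ng_event_log"))
  pr <- log$presses
  if (is.null(pr) || nrow(pr) == 0) stop("empty event log")
  isis <- tapply(pr$t_ms, pr$player, function(t) {
    t <- sort(t)
    if (length(t) < 2) Inf else min(diff(t))
  })
  w <- min(isis)
  if (!is.finite(w))
    stop("need at least one player with two or more presses")
  np <- max(pr$player)
  t0 <- min(c(pr$t_ms, log$trajectory$t_ms))

  bin <- floor((pr$t_ms - t0) / w + 1e-9)
  N <- max(bin) + 1L
  if (!is.null(log$trajectory) && nrow(log$trajectory) > 0)
    N <- max(N, as.integer(floor((max(log$trajectory$t_ms) - t0) / w + 1e-9)))

  A <- matrix(0L, N, np)
  cell <- cbind(bin + 1L, pr$player)
  if (anyDuplicated(cell))
    stop("a bin contains two presses of the same player; ",
         "impossible under the minimum-ISI bin width")
  A[cell] <- 1L

  S <- NULL
  if (!is.null(log$trajectory) && nrow(log$trajectory) > 0) {
    tr <- log$trajectory[order(log$trajectory$t_ms), ]
    bounds <- t0 + (0:N) * w
    idx <- findInterval(bounds + 1e-9, tr$t_ms)
    idx[idx == 0] <- 1
    S <- cbind(x = tr$x[idx], y = tr$y[idx])
  }
  list(A = A, S = S, bin_width_ms = w)
}

#' Reconstruct a session-like object from an event log
#'
#' Discretizes an event log and reassembles `ng_batch`/`ng_session`
#' structure from the batch and trial marker records, so that the full
#' metrics suite ([group_metrics()], [learning_metrics()]) applies to logs
#' in the human recording format.
#'
#' @param log An `ng_event_log` containing batch and trial records.
#' @param config Game configuration the log was recorded under.
#' @return An `ng_session` with model `"log"`.
#' @export
session_from_log <- function(log, config = game_config()) {
  stopifnot(inherits(log, "ng_event_log"),
            !is.null(log$batches), !is.null(log$trials))
  disc <- discretize_time(log)
  w <- disc$bin_width_ms
  t0 <- min(c(log$presses$t_ms, log$trajectory$t_ms))
  row_t <- t0 + (seq_len(nrow(disc$A)) - 1) * w
  np <- ncol(disc$A)

  batches <- list()
  for (b in seq_len(nrow(log$batches))) {
    tb0 <- log$batches$t_ms[b]
    tb1 <- if (b < nrow(log$batches)) log$batches$t_ms[b + 1] else Inf
    rows <- which(row_t >= tb0 - 1e-9 & row_t < tb1 - 1e-9)
    if (length(rows) == 0) next
    tr <- log$trials[log$trials$batch == b, , drop = FALSE]
    trial_of_row <- findInterval(row_t[rows], tr$t_ms + 1e-9) + 0L
    trial_of_row[trial_of_row == 0] <- 1L
    steps <- tabulate(trial_of_row, nbins = nrow(tr))
    mu <- as.numeric(log$batches[b, paste0("mu.", seq_len(np))])
    batches[[length(batches) + 1]] <- structure(list(
      actions = disc$A[rows, , drop = FALSE],
      pos = disc$S[rows, , drop = FALSE],
      pos_next = disc$S[rows + 1, , drop = FALSE],
      trial = trial_of_row,
      trials = data.frame(start_x = tr$start_x, start_y = tr$start_y,
                          target_x = tr$target_x, target_y = tr$target_y,
                          steps = steps, reached = NA),
      spikes = colSums(disc$A[rows, , drop = FALSE]),
      units = NULL, mu = mu, model = "log"), class = "ng_batch")
  }
  cfg <- config
  structure(list(model = "log", config = cfg, params = NULL, seed = NULL,
                 batches = batches), class = "ng_session")
}
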