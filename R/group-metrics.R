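# Cooperation statistics on action matrices and trajectories: success rates,
# counterfactual correct responses, event synchronization, action-time
# correlation, and the covariance-based cooperation measure.

# success indicator: strict improvement beyond delta
.succ_ind <- function(d0, d1, delta = 0) (d0 - d1) > delta

#' Group success rate
#'
#' Fraction of decision time points (rows with at least one active player)
#' where the group action reduced the cursor-target distance by more than
#' `delta`.  Idle rows do not enter the denominator; at `delta = 0` the
#' improvement must be strict, so exact cancellations count as failures.
#'
#' @param A Binary action matrix, steps x players.
#' @param S Trajectory matrix with `nrow(A) + 1` rows (positions before each
#'   step plus the final position).
#' @param target Target position (length 2) shared by all rows.
#' @param delta Minimum required improvement, pixels.
#' @param T Number of leading time points to include.
#' @return The success fraction, with attribute `n` (number of decision time
#'   points); `NA` with `attr(, "undefined") = TRUE` when there are none.
#' @export
success_rate <- function(A, S, target, delta = 0, T = nrow(A)) {
  stopifnot(delta >= 0, T <= nrow(A), nrow(S) == nrow(A) + 1)
  d <- sqrt((target[1] - S[, 1])^2 + (target[2] - S[, 2])^2)
  use <- seq_len(T)
  active <- rowSums(A[use, , drop = FALSE]) > 0
  if (!any(active)) {
    out <- NA_real_
    attr(out, "undefined") <- TRUE
    return(out)
  }
  succ <- .succ_ind(d[use], d[use + 1], delta)[active]
  out <- mean(succ)
  attr(out, "n") <- sum(active)
  out
}

#' Pairwise success probability
#'
#' Among time points where players `i` and `j` were both active, the
#' fraction where the group displacement improved the target distance by
#' more than `delta`.
#'
#' @inheritParams success_rate
#' @param i,j Player indices (equal `i = j` gives the player-conditional
#'   success rate).
#' @export
pairwise_success <- function(A, S, target, delta = 0, i, j) {
  stopifnot(nrow(S) == nrow(A) + 1)
  d <- sqrt((target[1] - S[, 1])^2 + (target[2] - S[, 2])^2)
  co <- A[, i] == 1 & A[, j] == 1
  if (!any(co)) {
    out <- NA_real_
    attr(out, "undefined") <- TRUE
    return(out)
  }
  mean(.succ_ind(d[-length(d)], d[-1], delta)[co])
}

#' Counterfactual correct-response rate of one player
#'
#' Among the time points where player `i` pressed, the fraction where a
#' single lone step of `step_length` along the player's true direction
#' `mu_i` would have strictly reduced the distance to the target -
#' independently of what the rest of the group did.
#'
#' @inheritParams success_rate
#' @param mu_i The player's true direction angle.
#' @param i Player index.
#' @param step_length Step length in pixels.
#' @export
correct_response_rate <- function(A, S, target, mu_i, i, step_length = 10) {
  stopifnot(nrow(S) >= nrow(A))
  spikes <- which(A[, i] == 1)
  if (length(spikes) == 0) {
    out <- NA_real_
    attr(out, "undefined") <- TRUE
    return(out)
  }
  sx <- S[spikes, 1]; sy <- S[spikes, 2]
  d0 <- sqrt((target[1] - sx)^2 + (target[2] - sy)^2)
  dcf <- sqrt((target[1] - (sx + step_length * cos(mu_i)))^2 +
              (target[2] - (sy + step_length * sin(mu_i)))^2)
  mean(d0 - dcf > 0)
}

#' Event synchronization between two spike trains
#'
#' Counts near-coincident spikes inside an adaptive window of half the
#' minimum surrounding inter-spike interval of either train, normalized by
#' `sqrt(m_i * m_j)`.  Exact coincidences contribute 1/2 in each direction;
#' boundary spikes use an infinite missing interval inside the minimum.
#' Identical trains score 1; trains further apart than every inter-spike
#' interval score 0.
#'
#' @param train_i,train_j Strictly increasing spike times (any common unit).
#' @return Synchronization in `[0, 1]`.
#' @export
event_synchronization <- function(train_i, train_j) {
  if (length(train_i) < 1 || length(train_j) < 1)
    stop("event synchronization needs non-empty spike trains")
  stopifnot(!is.unsorted(train_i, strictly = TRUE),
            !is.unsorted(train_j, strictly = TRUE))
  .ng_event_sync(as.numeric(train_i), as.numeric(train_j))
}

#' Action-time correlation matrix
#'
#' Sample Pearson correlation between the binary activity columns (on
#' binary data this equals the Spearman correlation - the phi coefficient).
#' Constant columns yield `NA` entries.
#'
#' @param A Binary action matrix.
#' @return Symmetric players x players correlation matrix.
#' @export
action_time_correlation <- function(A) {
  sds <- apply(A, 2, sd)
  C <- suppressWarnings(cor(A))
  C[sds == 0, ] <- NA_real_
  C[, sds == 0] <- NA_real_
  diag(C)[sds > 0] <- 1
  C
}

#' Cooperation measure of a group
#'
#' Sample covariance, over the strict upper triangle of the player-pair
#' matrices, between the action-time correlations and the pairwise success
#' probabilities.  Positive values indicate that pairs who press together
#' also tend to move the cursor towards the target; negative values indicate
#' a dysfunctional group.
#'
#' @param C Action-time correlation matrix ([action_time_correlation()]).
#' @param Ssucc Pairwise success-probability matrix.
#' @return The scalar cooperation measure.
#' @export
cooperation_measure <- function(C, Ssucc) {
  stopifnot(identical(dim(C), dim(Ssucc)))
  up <- upper.tri(C)
  cv <- C[up]; sv <- Ssucc[up]
  bad <- !is.finite(cv) | !is.finite(sv)
  if (any(bad)) {
    pr <- which(up, arr.ind = TRUE)[bad, , drop = FALSE]
    stop("undefined pair entries: ",
         paste(sprintf("(%d,%d)", pr[, 1], pr[, 2]), collapse = " "))
  }
  cov(cv, sv)
}

#' Mean event synchronization by angular distance
#'
#' Averages pairwise synchronization over player pairs bucketed by the
#' circular distance between their true movement directions (multiples of
#' `pi/4` for eight equiangular directions).  Cooperative groups show a
#' U-shape: highest synchronization for neighbouring directions, lowest for
#' opposing ones.
#'
#' @param ES Pairwise synchronization matrix.
#' @param mu Per-player direction angles.
#' @return Data frame with columns `distance` and `mean_es`.
#' @export
synchronization_by_distance <- function(ES, mu) {
  np <- length(mu)
  stopifnot(nrow(ES) == np)
  pairs <- which(upper.tri(ES), arr.ind = TRUE)
  d <- circular_distance(mu[pairs[, 1]], mu[pairs[, 2]])
  sector <- 2 * pi / np
  bucket <- round(d / sector)  # integer multiples of the sector width
  es <- ES[upper.tri(ES)]
  agg <- tapply(es, factor(bucket), mean, na.rm = TRUE)
  data.frame(distance = as.integer(names(agg)) * sector,
             mean_es = as.numeric(agg), row.names = NULL)
}

# ---------------------------------------------------------------------------
# session-level aggregation
# ---------------------------------------------------------------------------

# per-batch metric pieces; matrices are in raw player order
.batch_metrics <- function(batch, delta, step_length, es = TRUE) {
  A <- batch$actions
  np <- ncol(A)
  dd <- .batch_distances(batch)
  succ <- .succ_ind(dd[, 1], dd[, 2], delta)
  active <- rowSums(A) > 0

  co <- crossprod(A)                      # co-activity counts
  cosucc <- crossprod(A, A * succ)        # co-activity successes
  Ssucc <- ifelse(co > 0, cosucc / co, NA_real_)

  tg <- .batch_targets(batch)
  correct <- numeric(np); spikes <- numeric(np)
  for (i in seq_len(np)) {
    s <- A[, i] == 1
    spikes[i] <- sum(s)
    if (spikes[i] > 0) {
      dcf <- sqrt((tg[s, 1] - (batch$pos[s, 1] +
                               step_length * cos(batch$mu[i])))^2 +
                  (tg[s, 2] - (batch$pos[s, 2] +
                               step_length * sin(batch$mu[i])))^2)
      correct[i] <- sum(dd[s, 1] - dcf > 0)
    }
  }

  C <- action_time_correlation(A)
  ESm <- NULL
  if (es) {
    ESm <- diag(np)
    for (i in seq_len(np - 1)) {
      ti <- which(A[, i] == 1)
      for (j in (i + 1):np) {
        tj <- which(A[, j] == 1)
        ESm[i, j] <- ESm[j, i] <-
          if (length(ti) > 0 && length(tj) > 0) .ng_event_sync(ti, tj)
          else NA_real_
      }
    }
  }

  up <- upper.tri(C)
  zeta <- if (all(is.finite(C[up])) && all(is.finite(Ssucc[up])))
    cov(C[up], Ssucc[up]) else NA_real_

  list(n_decisions = sum(active), n_success = sum(succ[active]),
       spikes = spikes, correct = correct,
       C = C, Ssucc = Ssucc, ES = ESm, zeta = zeta, mu = batch$mu)
}

#' Cooperation metrics of a simulated session
#'
#' Computes the full cooperation report for an `ng_session` (or a session
#' reconstructed from an event log): the pooled group success rate over
#' decision time points, per-player counterfactual correct-response rates,
#' pairwise matrices (action-time correlation, event synchronization,
#' pairwise success), the cooperation measure, and the
#' synchronization-by-distance profile.  Because the direction assignment -
#' and with it the pair structure - changes every batch, the pairwise
#' matrices are computed per batch, relabelled by the rank of each player's
#' direction angle, and averaged across batches; the cooperation measure is
#' the covariance between the two averaged matrices (per-batch values are
#' also reported as a diagnostic).
#'
#' @param session An `ng_session`.
#' @param delta Minimum required improvement (pixels) for a success.
#' @param es Compute event synchronization (the most expensive part).
#' @return An `ng_metrics` object.
#' @export
group_metrics <- function(session, delta = 0, es = TRUE) {
  stopifnot(inherits(session, "ng_session"))
  cfg <- session$config
  np <- cfg$n_players
  per <- lapply(session$batches, .batch_metrics, delta = delta,
                step_length = cfg$step_length, es = es)

  n_dec <- sum(vapply(per, `[[`, 0, "n_decisions"))
  n_suc <- sum(vapply(per, `[[`, 0, "n_success"))
  spikes <- Reduce(`+`, lapply(per, `[[`, "spikes"))
  correct <- Reduce(`+`, lapply(per, `[[`, "correct"))
  rates <- ifelse(spikes > 0, correct / spikes, NA_real_)

  zetas <- vapply(per, `[[`, 0, "zeta")

  # direction-rank relabelling for averaged matrices
  avg_mat <- function(field) {
    acc <- matrix(0, np, np); cnt <- matrix(0, np, np)
    for (p in per) {
      M <- p[[field]]
      if (is.null(M)) next
      o <- order(p$mu)
      M <- M[o, o]
      ok <- is.finite(M)
      acc[ok] <- acc[ok] + M[ok]
      cnt <- cnt + ok
    }
    ifelse(cnt > 0, acc / cnt, NA_real_)
  }

  es_profile <- NULL
  if (es) {
    prof <- do.call(rbind, lapply(per, function(p)
      synchronization_by_distance(p$ES, p$mu)))
    es_profile <- stats::aggregate(mean_es ~ distance, prof, mean)
  }

  Cbar <- avg_mat("C")
  Sbar <- avg_mat("Ssucc")
  zeta <- if (all(is.finite(Cbar[upper.tri(Cbar)])) &&
              all(is.finite(Sbar[upper.tri(Sbar)])))
    cooperation_measure(Cbar, Sbar) else NA_real_

  structure(list(
    model = session$model, delta = delta,
    success_rate = n_suc / n_dec, n_decisions = n_dec,
    correct_response = rates,
    mean_correct_response = mean(rates, na.rm = TRUE),
    synergy = n_suc / n_dec - mean(rates, na.rm = TRUE),
    zeta = zeta,
    zeta_per_batch = zetas,
    n_zeta_undefined = sum(!is.finite(zetas)),
    correlation = Cbar,
    pairwise_success = Sbar,
    event_sync = if (es) avg_mat("ES") else NULL,
    es_profile = es_profile
  ), class = "ng_metrics")
}

#' @export
print.ng_metrics <- function(x, ...) {
  cat(sprintf("Cooperation metrics (%s model, delta = %g px)\n",
              x$model, x$delta))
  cat(sprintf("  success rate      : %.1f%%  (%d decision steps)\n",
              100 * x$success_rate, x$n_decisions))
  cat(sprintf("  correct responses : %.1f%% mean across players\n",
              100 * x$mean_correct_response))
  cat(sprintf("  group synergy     : %+.1f points\n", 100 * x$synergy))
  cat(sprintf("  cooperation zeta  : %.4f  (%d batches undefined)\n",
              x$zeta, x$n_zeta_undefined))
  invisible(x)
}

#' Success rate as a function of the improvement threshold
#'
#' Sweeps the minimum-improvement threshold `delta`, expressed as a
#' dimensionless fraction of display size, and reports the group success
#' rate at each value.  Display size is the screen width by default (the
#' diagonal is available as an alternative normalization).
#'
#' @param session An `ng_session`.
#' @param deltas Threshold grid as fractions of display size.
#' @param normalize `"width"` or `"diagonal"`.
#' @return Data frame with `delta_fraction`, `delta_px`, `success_rate`.
#' @export
success_sweep <- function(session, deltas = seq(0, 0.028, by = 0.002),
                          normalize = c("width", "diagonal")) {
  normalize <- match.arg(normalize)
  cfg <- session$config
  size <- if (normalize == "width") cfg$screen_width
          else sqrt(cfg$screen_width^2 + cfg$screen_height^2)
  rows <- lapply(deltas, function(fr) {
    m <- group_metrics(session, delta = fr * size, es = FALSE)
    data.frame(delta_fraction = fr, delta_px = fr * size,
               success_rate = m$success_rate)
  })
  do.call(rbind, rows)
}
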