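# Learning-progress analyses: spike-triggered average/variance, learning
# duration, population-vector decoding error, cumulative-exponential fits.

#' Spike-triggered average direction of one player
#'
#' Circular mean of the target-difference angles present at the player's
#' spike times up to time `t`.  The stimulus is the noiseless on-screen
#' angle, not the unit's private noisy observation.
#'
#' @param A_i Binary spike indicator vector of one player.
#' @param stimuli Target-difference angles per time point (radians).
#' @param t Time index up to which spikes are counted.
#' @return The circular mean angle, or `NA` with `attr(, "undefined")` when
#'   there are no spikes or the resultant vanishes.
#' @export
spike_triggered_average <- function(A_i, stimuli, t = length(A_i)) {
  stopifnot(length(A_i) == length(stimuli), t >= 1, t <= length(A_i))
  s <- which(A_i[seq_len(t)] == 1)
  if (length(s) == 0) {
    out <- NA_real_; attr(out, "undefined") <- TRUE; return(out)
  }
  m <- .circ_mean(stimuli[s])
  if (is.na(m)) attr(m, "undefined") <- TRUE
  m
}

#' Spike-triggered variance
#'
#' One minus the resultant length of the spike-conditioned stimulus angles:
#' 0 for perfectly repeated stimuli, approaching 1 for uniformly spread
#' ones.  The value is the dimensionless circular variance.
#'
#' @inheritParams spike_triggered_average
#' @export
spike_triggered_variance <- function(A_i, stimuli, t = length(A_i)) {
  stopifnot(length(A_i) == length(stimuli), t >= 1, t <= length(A_i))
  s <- which(A_i[seq_len(t)] == 1)
  if (length(s) == 0) {
    out <- NA_real_; attr(out, "undefined") <- TRUE; return(out)
  }
  1 - sqrt(mean(sin(stimuli[s]))^2 + mean(cos(stimuli[s]))^2)
}

# running STA/STV over the spike ordinals of one player
.sta_series <- function(spike_angles) {
  k <- seq_along(spike_angles)
  cs <- cumsum(cos(spike_angles)) / k
  sn <- cumsum(sin(spike_angles)) / k
  res <- sqrt(cs^2 + sn^2)
  sta <- ifelse(res < 1e-12, NA_real_, .wrap2pi(atan2(sn, cs)))
  list(sta = sta, stv = 1 - res)
}

#' Learning duration of one player
#'
#' The smallest spike index from which onward the running spike-triggered
#' average stays within `pi/2` of the player's true movement direction at
#' every later spike.  Censored (with `attr(, "censored")`) when the
#' condition is never met within the series.
#'
#' @param sta_series Running STA angles, one per spike ordinal (`NA` entries
#'   count as outside the neighbourhood).
#' @param mu_i True movement direction.
#' @return Spike index, or `NA` flagged as censored.
#' @export
learning_duration <- function(sta_series, mu_i) {
  stopifnot(length(sta_series) >= 1)
  ok <- !is.na(sta_series) & circular_distance(sta_series, mu_i) <= pi / 2
  if (!any(!ok)) return(1L)
  last_bad <- max(which(!ok))
  if (last_bad == length(ok)) {
    out <- NA_integer_; attr(out, "censored") <- TRUE; return(out)
  }
  last_bad + 1L
}

#' Population-vector decoding
#'
#' Projects a stimulus vector onto the (generally overcomplete) system of
#' unit axes given by the players' spike-triggered averages and sums the
#' projections: `v_pop = sum_i <v, e_i> e_i`.  For eight exactly equiangular
#' axes this is a tight frame and preserves the stimulus angle.
#'
#' @param v Stimulus vector (length 2).
#' @param sta_angles Per-player STA angles; all must be defined.
#' @return The population vector (length 2).
#' @export
population_decode <- function(v, sta_angles) {
  if (any(!is.finite(sta_angles)))
    stop("undefined spike-triggered average; exclude these time points")
  e <- cbind(cos(sta_angles), sin(sta_angles))
  colSums(as.numeric(e %*% v) * e)
}

#' Average population decoding error
#'
#' Mean circular distance between the angles of the population vector and
#' of the true target-difference vector over the supplied time points.
#' Time points with a vanishing population vector contribute `pi/2`.
#'
#' @param v_mat Stimulus vectors, one row per time point.
#' @param sta_angles Per-player STA angles.
#' @return Mean angular error in `[0, pi]`.
#' @export
decoding_error <- function(v_mat, sta_angles) {
  if (any(!is.finite(sta_angles)))
    stop("undefined spike-triggered average; exclude these time points")
  v_mat <- rbind(v_mat)
  e <- cbind(cos(sta_angles), sin(sta_angles))
  M <- crossprod(e)          # 2x2 frame operator sum e_i e_i^T
  vp <- v_mat %*% M
  len <- sqrt(rowSums(vp^2))
  err <- ifelse(len < 1e-12, pi / 2,
                circular_distance(atan2(vp[, 2], vp[, 1]),
                                  atan2(v_mat[, 2], v_mat[, 1])))
  mean(err)
}

#' Fit a cumulative-exponential learning curve
#'
#' Least-squares fit of `F(k) = 1 - exp(-r k)` to the empirical fraction of
#' unit-batches whose learning duration is at most `k` spikes.  Censored
#' durations are excluded from the fit (but reported by the callers).
#'
#' @param durations Learning durations in spikes.
#' @param censored Logical censor flags (censored entries are dropped).
#' @return The rate `r`, with attribute `boundary` when the fit is pinned at
#'   the search boundary (degenerate data).
#' @export
fit_learning_curve <- function(durations, censored = rep(FALSE, length(durations))) {
  d <- durations[!censored & !is.na(durations)]
  if (length(d) < 5) stop("need at least 5 uncensored durations")
  kmax <- max(d)
  k <- seq_len(kmax)
  Fhat <- vapply(k, function(kk) mean(d <= kk), 0)
  obj <- function(lr) sum((Fhat - (1 - exp(-exp(lr) * k)))^2)
  opt <- optimize(obj, lower = log(1e-4), upper = log(10))
  r <- exp(opt$minimum)
  if (opt$minimum < log(1e-4) + 1e-6 || opt$minimum > log(10) - 1e-6)
    attr(r, "boundary") <- TRUE
  if (length(unique(d)) == 1) attr(r, "boundary") <- TRUE
  r
}

#' Learning metrics of a simulated session
#'
#' For every unit and batch: the running spike-triggered average and
#' variance over spike ordinals, the learning duration (first spike index
#' from which the STA permanently stays within `pi/2` of the true
#' direction), the whole-batch STA, and the population decoding error of the
#' group evaluated with whole-batch STAs over the late portion of each
#' batch.  Summaries: the fraction of unit-batches with duration at most
#' `duration_cut` spikes, the fitted cumulative-exponential learning rate,
#' the mean decoding error, and batch-averaged STV at selected spike
#' ordinals.
#'
#' @param session An `ng_session`.
#' @param duration_cut Spike-count threshold for the converged fraction.
#' @param late_fraction Fraction of each batch's final time points used for
#'   the decoding error.
#' @return An `ng_learning` object.
#' @export
learning_metrics <- function(session, duration_cut = 50, late_fraction = 0.5) {
  stopifnot(inherits(session, "ng_session"))
  np <- session$config$n_players
  durations <- c(); censored <- c()
  decode_errs <- c()
  stv_at <- list()
  sta_final <- list()

  for (batch in session$batches) {
    A <- batch$actions
    tg <- .batch_targets(batch)
    psi <- .wrap2pi(atan2(tg[, 2] - batch$pos[, 2],
                          tg[, 1] - batch$pos[, 1]))
    whole_sta <- rep(NA_real_, np)
    for (i in seq_len(np)) {
      s <- which(A[, i] == 1)
      if (length(s) == 0) next
      ser <- .sta_series(psi[s])
      dur <- learning_duration(ser$sta, batch$mu[i])
      durations <- c(durations, if (is.na(dur)) NA else dur)
      censored <- c(censored, is.na(dur))
      stv_at[[length(stv_at) + 1]] <- ser$stv
      whole_sta[i] <- .circ_mean(psi[s])
    }
    sta_final[[length(sta_final) + 1]] <- whole_sta
    if (all(is.finite(whole_sta))) {
      N <- nrow(A)
      late <- seq.int(max(1L, floor((1 - late_fraction) * N) + 1L), N)
      v <- cbind(tg[late, 1] - batch$pos[late, 1],
                 tg[late, 2] - batch$pos[late, 2])
      decode_errs <- c(decode_errs, decoding_error(v, whole_sta))
    }
  }

  # fraction among uncensored durations: the empirical CDF the
  # cumulative-exponential fit describes (censored batches end before the
  # criterion can be evaluated and are reported separately)
  frac_within <- mean(durations[!censored] <= duration_cut)
  rate <- tryCatch(fit_learning_curve(durations, censored),
                   error = function(e) NA_real_)
  stv_ordinal <- function(k) {
    v <- vapply(stv_at, function(s) if (length(s) >= k) s[k] else NA_real_, 0)
    mean(v, na.rm = TRUE)
  }

  structure(list(
    model = session$model,
    durations = durations, censored = censored,
    duration_cut = duration_cut,
    frac_within_cut = frac_within,
    learning_rate = rate,
    decoding_error = mean(decode_errs),
    decoding_error_per_batch = decode_errs,
    stv_spike5 = stv_ordinal(5), stv_spike100 = stv_ordinal(100),
    sta_final = sta_final
  ), class = "ng_learning")
}

#' @export
print.ng_learning <- function(x, ...) {
  cat(sprintf("Learning metrics (%s model)\n", x$model))
  cat(sprintf("  unit-batches with T* <= %d spikes: %.1f%% (%d censored of %d)\n",
              x$duration_cut, 100 * x$frac_within_cut, sum(x$censored),
              length(x$durations)))
  cat(sprintf("  fitted learning rate r           : %.4f per spike\n",
              x$learning_rate))
  cat(sprintf("  population decoding error        : %.3f rad\n",
              x$decoding_error))
  cat(sprintf("  mean STV at spike 5 / 100        : %.3f / %.3f\n",
              x$stv_spike5, x$stv_spike100))
  invisible(x)
}
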