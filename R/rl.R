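#' SARSA(lambda) unit state
#'
#' Weight vector over the stacked (idle | press) tile features and the
#' replacing eligibility trace.  Layout: entries `1..nm` belong to action 0,
#' entries `nm+1..2nm` to action 1.
#'
#' @param params [agent_params()] (uses `n_tiles`, `n_tilings`, `alpha`,
#'   `gamma`, `lambda`).
#' @return An `ng_rl_state` object.
#' @export
rl_state <- function(params = agent_params("rl")) {
  nm <- params$n_tiles * params$n_tilings
  structure(list(w = numeric(2 * nm), z = numeric(2 * nm),
                 alpha = params$alpha, gamma = params$gamma,
                 lambda = params$lambda, nm = nm),
            class = "ng_rl_state")
}

#' SARSA activation level
#'
#' Difference of the state-action values for pressing versus idling:
#' `g = Q(f, 1) - Q(f, 0) = w1.f - w0.f`.
#'
#' @param state An `ng_rl_state`.
#' @param f Feature vector from [encode_angle()].
#' @export
rl_activation <- function(state, f) {
  idx <- attr(f, "active")
  if (is.null(idx)) idx <- which(f == 1L)
  sum(state$w[state$nm + idx]) - sum(state$w[idx])
}

#' One SARSA(lambda) update with replacing traces
#'
#' Applies, in order: trace replacement `z <- max(z, f~_t(a_t))`, the
#' temporal-difference weight update
#' `w <- w + alpha * z * (r - w.f~_t(a_t) + gamma * w.f~_{t+1}(a_{t+1}))`,
#' and the trace decay `z <- gamma * lambda * z`.  For a terminal transition
#' the bootstrap term is dropped.
#'
#' @param state An `ng_rl_state`.
#' @param f_t,a_t Feature vector and action at the update step.
#' @param r Reward observed for the transition (-1, 0 or +1).
#' @param f_t1,a_t1 Next feature vector and action (ignored when
#'   `terminal`).
#' @param terminal Whether the transition ended the episode.
#' @return The updated state.
#' @export
sarsa_update <- function(state, f_t, a_t, r, f_t1 = NULL, a_t1 = 0L,
                         terminal = FALSE) {
  idx_t <- attr(f_t, "active")
  if (is.null(idx_t)) idx_t <- which(f_t == 1L)
  idx_t1 <- if (terminal || is.null(f_t1)) integer(0) else {
    i <- attr(f_t1, "active")
    if (is.null(i)) which(f_t1 == 1L) else i
  }
  if (any(idx_t > state$nm) || any(idx_t1 > state$nm))
    stop("feature indices exceed the feature length")
  res <- .ng_sarsa_update(state$w, state$z, as.integer(idx_t),
                          as.integer(a_t), as.numeric(r),
                          as.integer(idx_t1), as.integer(a_t1),
                          isTRUE(terminal), state$alpha, state$gamma,
                          state$lambda, state$nm)
  state$w <- res$w
  state$z <- res$z
  state
}

#' Perceptron unit state
#'
#' @param params [agent_params()] (uses `n_tiles`, `n_tilings`, `alpha`,
#'   `perceptron_variant`).
#' @return An `ng_perceptron_state` with zero weights and bias.
#' @export
perceptron_state <- function(params = agent_params("ann")) {
  nm <- params$n_tiles * params$n_tilings
  structure(list(w = numeric(nm), b = 0, alpha = params$alpha,
                 variant = params$perceptron_variant, nm = nm),
            class = "ng_perceptron_state")
}

#' Perceptron activation level
#'
#' `g = w.f + b`.
#'
#' @param state An `ng_perceptron_state`.
#' @param f Feature vector.
#' @export
perceptron_activation <- function(state, f) {
  idx <- attr(f, "active")
  if (is.null(idx)) idx <- which(f == 1L)
  sum(state$w[idx]) + state$b
}

#' Perceptron learning update
#'
#' Applied only on steps where the unit pressed (`y = 1`).  With the
#' training signal `T = 1` (the group displacement reduced the target
#' distance) nothing changes; with `T = 0` the update is punitive.  The
#' default `feature_based` variant subtracts `alpha` from the weights of the
#' active features and from the bias; the `as_printed` variant multiplies
#' weights and bias by `1 - alpha`, which never leaves the all-zero
#' initialization.
#'
#' @param state An `ng_perceptron_state`.
#' @param f Feature vector at the spike.
#' @param spiked Whether the unit pressed (`y`); no update otherwise.
#' @param T Binary training signal.
#' @return The updated state.
#' @export
perceptron_update <- function(state, f, spiked, T) {
  if (!isTRUE(as.logical(spiked))) return(state)
  idx <- attr(f, "active")
  if (is.null(idx)) idx <- which(f == 1L)
  res <- .ng_perceptron_update(state$w, state$b, as.integer(idx),
                               as.integer(T), state$alpha,
                               identical(state$variant, "as_printed"))
  state$w <- res$w
  state$b <- res$b
  state
}
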