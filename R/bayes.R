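#' Utility of acting given observation and displacement direction
#'
#' Acting is worth the expected reduction in target distance, expressed
#' through angles: `U(1, phi, nu) = pi/2 - d_C(phi, nu)`; staying idle is
#' worth nothing.
#'
#' @param a Action, 0 or 1.
#' @param phi Observed target-difference angle.
#' @param nu Hypothesized displacement direction.
#' @return Utility in `[-pi/2, pi/2]`.
#' @export
utility <- function(a, phi, nu) {
  if (a == 0) return(0)
  pi / 2 - circular_distance(phi, nu)
}

#' Initialize an uninformed displacement-direction belief
#'
#' The belief over a unit's hidden displacement direction is summarized by a
#' resultant length `R0`, a mean direction `Phi` (undefined while `R0 = 0`),
#' and an observation count `c`.  Fresh units start at
#' `R0 = 0, Phi = NA, c = 0`.
#'
#' @return An `ng_belief` object.
#' @export
belief_init <- function() {
  structure(list(R0 = 0, Phi = NA_real_, c = 0), class = "ng_belief")
}

#' Update a belief with observed displacement angles
#'
#' Unit vectors of the new observation angles are added to the belief's
#' resultant vector; the count increases by the number of observations.
#'
#' @param belief An `ng_belief`.
#' @param angles Observed displacement angles (radians).
#' @return The updated belief.
#' @export
belief_update <- function(belief, angles) {
  stopifnot(inherits(belief, "ng_belief"), all(is.finite(angles)))
  s <- if (belief$R0 > 0 && is.finite(belief$Phi))
    belief$R0 * sin(belief$Phi) else 0
  co <- if (belief$R0 > 0 && is.finite(belief$Phi))
    belief$R0 * cos(belief$Phi) else 0
  s <- s + sum(sin(angles))
  co <- co + sum(cos(angles))
  R0 <- sqrt(s^2 + co^2)
  belief$R0 <- R0
  belief$Phi <- if (R0 > 1e-12) .wrap2pi(atan2(s, co)) else NA_real_
  belief$c <- belief$c + length(angles)
  belief
}

#' @export
print.ng_belief <- function(x, ...) {
  cat(sprintf("Direction belief: R0 = %.3f, Phi = %s, c = %g\n", x$R0,
              if (is.finite(x$Phi)) sprintf("%.3f rad", x$Phi) else "undefined",
              x$c))
  invisible(x)
}

.belief_check <- function(belief) {
  stopifnot(inherits(belief, "ng_belief"))
  if (belief$R0 > 1e-12 && !is.finite(belief$Phi))
    stop("belief has positive resultant length but undefined mean direction")
  invisible(belief)
}

#' Belief density on the (direction, concentration) grid
#'
#' The joint density over displacement direction `nu` and von Mises
#' concentration `kappa` is `p(nu, kappa) proportional to
#' exp(kappa * R0 * cos(Phi - nu)) / I0(kappa)^c`, normalized numerically on
#' a grid: `nu_grid` even midpoints over `[0, 2*pi)` and a logarithmic
#' `kappa` grid on `(kappa_min, kappa_max]`.  The modified Bessel function
#' `I0` is evaluated exactly below a switch point and by its asymptotic
#' equivalent `exp(kappa)/sqrt(2*pi*kappa)` above it.
#'
#' @param belief An `ng_belief`.
#' @param params [agent_params()] carrying the grid sizes.
#' @return List with `nu`, `kappa`, `kappa_width`, the joint `density`
#'   matrix (`nu` rows, `kappa` columns, integrating to 1 against the grid
#'   cell areas), and the `nu_marginal` (density over `[0, 2*pi)`).
#' @export
belief_density <- function(belief, params = agent_params("bayes")) {
  .belief_check(belief)
  grid <- .ng_kappa_grid(params$kappa_grid_size, params$kappa_min,
                         params$kappa_max)
  nnu <- params$nu_grid
  nu <- (seq_len(nnu) - 0.5) * 2 * pi / nnu
  dnu <- 2 * pi / nnu
  Phi <- if (is.finite(belief$Phi)) belief$Phi else 0
  # log density up to a constant, column per kappa grid point
  logd <- outer(cos(nu - Phi), belief$R0 * grid$kappa) -
    rep(belief$c * .ng_log_i0(grid$kappa), each = nnu)
  d <- exp(logd - max(logd))
  z <- sum(sweep(d, 2, grid$width, "*")) * dnu
  d <- d / z
  marg <- as.numeric(d %*% grid$width)
  list(nu = nu, kappa = grid$kappa, kappa_width = grid$width,
       density = d, nu_marginal = marg)
}

#' Bayesian activation: expected utility of acting
#'
#' Numerically integrates the utility of acting over the belief
#' `p(nu, kappa)` and the feature-conditional angle density `p(phi | f)`
#' (idle actions have zero utility, so the expected utility of acting is the
#' activation level itself).
#'
#' @param belief An `ng_belief`.
#' @param f A feature vector from [encode_angle()], or a single angle taken
#'   directly as the centre of the feature support.
#' @param params [agent_params()].
#' @return Scalar activation level.
#' @export
bayes_activation <- function(belief, f, params = agent_params("bayes")) {
  .belief_check(belief)
  phibar <- if (length(f) == 1) as.numeric(f) else {
    pf <- phi_given_features(f, params$n_tiles, params$n_tilings)
    pf$center
  }
  g <- .ng_bayes_activation(belief$R0,
                            if (is.finite(belief$Phi)) belief$Phi else 0,
                            belief$c, phibar,
                            params$n_tiles, params$n_tilings,
                            params$nu_grid, params$kappa_grid_size,
                            params$kappa_min, params$kappa_max,
                            params$phi_quadrature)
  if (!is.finite(g)) stop("Bayesian quadrature returned a non-finite value")
  g
}

#' Thompson activation: one posterior sample of the utility
#'
#' Draws `phi'` from the feature-conditional angle density and
#' `(nu', kappa')` from the belief, and returns `U(1, phi', nu')`.  Its mean
#' over repeated draws equals the Bayesian activation for the same state.
#'
#' @inheritParams bayes_activation
#' @export
thompson_activation <- function(belief, f, params = agent_params("thompson")) {
  .belief_check(belief)
  phibar <- if (length(f) == 1) as.numeric(f) else {
    pf <- phi_given_features(f, params$n_tiles, params$n_tilings)
    pf$center
  }
  .ng_thompson_activation(belief$R0,
                          if (is.finite(belief$Phi)) belief$Phi else 0,
                          belief$c, phibar,
                          params$n_tiles, params$n_tilings,
                          params$kappa_grid_size,
                          params$kappa_min, params$kappa_max)
}

#' Sign reward of a cursor transition
#'
#' `+1` when the cursor moved closer to the target, `-1` when it moved away,
#' `0` when the distance is unchanged.
#'
#' @param s_t,s_t1 Cursor positions before and after the step.
#' @param target Target position.
#' @export
reward_sign <- function(s_t, s_t1, target) {
  d0 <- sqrt(sum((target - s_t)^2))
  d1 <- sqrt(sum((target - s_t1)^2))
  sign(d0 - d1)
}
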