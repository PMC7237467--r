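#' Circular distance between two angles
#'
#' `d_C(a, b) = min(|a - b|, 2*pi - |a - b|)`, in radians, after wrapping both
#' angles to `[0, 2*pi)`.  Vectorized over both arguments.
#'
#' @param a,b Angles in radians.
#' @return Distances in `[0, pi]`.
#' @export
circular_distance <- function(a, b) {
  d <- abs((a %% (2 * pi)) - (b %% (2 * pi)))
  pmin(d, 2 * pi - d)
}

.wrap2pi <- function(x) x %% (2 * pi)

# circular mean of a set of angles; NA when the resultant vanishes
.circ_mean <- function(ang) {
  s <- sum(sin(ang)); c <- sum(cos(ang))
  if (sqrt(s^2 + c^2) < 1e-12) return(NA_real_)
  .wrap2pi(atan2(s, c))
}

#' Observe the target-difference angle
#'
#' Computes the true target-difference angle `psi = atan2(ty - sy, tx - sx)`
#' and its noisy representation `phi = (psi + eta) mod 2*pi`, with
#' `eta ~ Normal(0, beta3)` (`beta3` is a variance in rad^2).
#'
#' @param target,cursor Numeric length-2 positions.
#' @param beta3 Observation-noise variance; `0` gives `phi == psi`.
#' @return List with `psi` and `phi`, both in `[0, 2*pi)`.
#' @export
observe <- function(target, cursor, beta3 = 0) {
  if (isTRUE(all(target == cursor)))
    stop("target and cursor coincide; the observation angle is undefined")
  psi <- .wrap2pi(atan2(target[2] - cursor[2], target[1] - cursor[1]))
  phi <- .wrap2pi(psi + rnorm(1, 0, sqrt(beta3)))
  list(psi = psi, phi = phi)
}

#' Tile-code an angle into a binary feature vector
#'
#' The angle is encoded with `m` tilings of `n` tiles each: tiling `j` is the
#' partition of the circle into `n` equal arcs shifted by `j/m` of a tile, so
#' exactly one tile per tiling is active and the feature vector of length
#' `n*m` has exactly `m` ones.  The encoding is 2*pi-periodic and piecewise
#' constant with breakpoints every `2*pi/(n*m)`.
#'
#' @param phi Angle in radians.
#' @param n Tiles per tiling.
#' @param m Number of tilings.
#' @return Binary integer vector of length `n*m`, with attributes `active`
#'   (the 1-based indices of the active tiles, tiling-major layout) and
#'   `phibar` (circular mean of the active tile centres, used as the centre
#'   of the feature's angular support).
#' @export
encode_angle <- function(phi, n = 8, m = 45) {
  stopifnot(length(phi) == 1, is.finite(phi))
  idx <- .ng_encode_idx(phi, n, m)
  f <- integer(n * m)
  f[idx] <- 1L
  attr(f, "active") <- idx
  attr(f, "phibar") <- .ng_phibar(phi, n, m)
  f
}

# tile centre angles for 1-based flat indices under the tiling-major layout
.tile_centers <- function(idx, n, m) {
  j <- (idx - 1L) %/% n + 1L   # tiling
  i0 <- (idx - 1L) %% n        # tile within the tiling, 0-based
  .wrap2pi(2 * pi * (i0 + j / m + 0.5) / n)
}

#' Angular density compatible with a feature vector
#'
#' The set of angles consistent with a tile-coded feature vector is the
#' intersection of its active tiles: an arc of width `2*pi/(n*m)` centred at
#' the circular mean of the active tile centres.  The conditional density is
#' uniform on that arc with value `n*m/(2*pi)`.
#'
#' @param f A binary feature vector produced by [encode_angle()] (or any
#'   vector of length `n*m` with exactly one active tile per tiling).
#' @param n,m Tile-coding layout.
#' @return List with `center`, `halfwidth` (`pi/(n*m)`), `density`
#'   (`n*m/(2*pi)`), and a vectorized density function `pdf(phi)`.
#' @export
phi_given_features <- function(f, n = 8, m = 45) {
  nm <- n * m
  if (length(f) != nm || sum(f) != m)
    stop("degenerate feature vector: need length ", nm, " with exactly ", m,
         " ones")
  idx <- which(f == 1L)
  blocks <- (idx - 1L) %/% n
  if (!identical(as.integer(blocks), 0:(m - 1L)))
    stop("degenerate feature vector: need exactly one active tile per tiling")
  center <- .circ_mean(.tile_centers(idx, n, m))
  hw <- pi / nm
  dens <- nm / (2 * pi)
  pdf <- function(phi) ifelse(circular_distance(phi, center) < hw, dens, 0)
  list(center = center, halfwidth = hw, density = dens, pdf = pdf)
}

#' Exploration rate as a function of spike count
#'
#' Units explore (press at random) with probability `epsilon`, which decays
#' geometrically in the number of spikes already produced and is bounded
#' below by `beta2`: `epsilon = max(beta2, epsilon_base^c)`.
#'
#' @param c Spike count (vectorized).
#' @param beta2 Exploration floor.
#' @param epsilon_base Decay base per spike.
#' @export
exploration_rate <- function(c, beta2 = 0.05, epsilon_base = 0.85) {
  stopifnot(all(c >= 0))
  pmax(beta2, epsilon_base^c)
}

#' Action probability of a decision unit
#'
#' `P(a = 1) = (1 - q) * (epsilon/2 + (1 - epsilon) * sigma(g))` with the
#' soft activation `sigma(x) = atan(gain * x)/pi + 1/2`.  The `q`-gate forces
#' the unit idle with probability `q` regardless of its activation,
#' emulating the refractory statistics of the original button presses.
#'
#' @param g Activation level (vectorized).
#' @param epsilon Exploration rate in `[0, 1]`.
#' @param q Forced-idle probability.
#' @param gain Gain of the soft activation.
#' @return Probability of pressing, in `[0, 1 - q]`.
#' @export
action_probability <- function(g, epsilon, q = 0.1939, gain = 5) {
  stopifnot(all(is.finite(g)), all(epsilon >= 0 & epsilon <= 1))
  sig <- atan(gain * g) / pi + 0.5
  (1 - q) * (epsilon / 2 + (1 - epsilon) * sig)
}
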