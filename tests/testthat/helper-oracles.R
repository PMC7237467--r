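# Independent brute-force oracles used to cross-check the implementation.

# success rate by explicit looping over time points
brute_success <- function(A, S, target, delta = 0) {
  n_dec <- 0; n_suc <- 0
  for (t in seq_len(nrow(A))) {
    if (sum(A[t, ]) >= 1) {
      n_dec <- n_dec + 1
      d0 <- sqrt(sum((target - S[t, ])^2))
      d1 <- sqrt(sum((target - S[t + 1, ])^2))
      if (d0 - d1 > delta) n_suc <- n_suc + 1
    }
  }
  if (n_dec == 0) return(NA_real_)
  n_suc / n_dec
}

# event synchronization by direct evaluation of the defining sums
brute_es <- function(ti, tj) {
  mi <- length(ti); mj <- length(tj)
  isi <- function(tt, k) {
    c(if (k > 1) tt[k] - tt[k - 1] else Inf,
      if (k < length(tt)) tt[k + 1] - tt[k] else Inf)
  }
  total <- 0
  for (k in seq_len(mi)) for (l in seq_len(mj)) {
    tau <- min(c(isi(ti, k), isi(tj, l))) / 2
    d <- ti[k] - tj[l]
    if (d == 0) total <- total + 1            # 1/2 in each direction
    else if (d > 0 && d <= tau) total <- total + 1
    else if (d < 0 && -d <= tau) total <- total + 1
  }
  total / sqrt(mi * mj)
}

# population vector by the direct eight-term summation
brute_decode <- function(v, angles) {
  out <- c(0, 0)
  for (i in seq_along(angles)) {
    e <- c(cos(angles[i]), sin(angles[i]))
    out <- out + sum(v * e) * e
  }
  out
}

# one small simulated session per model, shared across test files
.ng_cache <- new.env(parent = emptyenv())
cached_session <- function(model, n_batches = 4, seed = 99) {
  key <- paste(model, n_batches, seed)
  if (is.null(.ng_cache[[key]])) {
    .ng_cache[[key]] <- run_session(model, game_config(n_batches = n_batches),
                                    agent_params(model, beta3 = 0.1,
                                                 gain = 8, beta2 = 0.01,
                                                 beta1 = 1),
                                    seed = seed)
  }
  .ng_cache[[key]]
}
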