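# Independent oracles and fixture builders used across the suite.

# Closed-form mean/variance of the linear birth-death process
# (constant per-capita rates b, d; g = b - d != 0).
bd_closed_form <- function(b, d, N0, t) {
  g <- b - d
  m <- N0 * exp(g * t)
  v <- N0 * ((b + d) / g) * exp(g * t) * (exp(g * t) - 1)
  list(mean = m, variance = v)
}

# Closed-form moments of the strong-Allee process (linear propensities
# bN - gA etc. taken at face value, i.e. ignoring clamping):
#   M(t) = A + (N0 - A) e^{gt}
#   S(t) = e^{2gt} [ ((b+d+s*g) A / (2g)) (1 - e^{-2gt})
#                    + ((b+d)(N0-A)/g) (1 - e^{-gt}) ]
# with s = -1 (birth), +1 (death), 0 (both).
strong_closed_form <- function(b, d, A, N0, t, effect = c("birth", "death", "both")) {
  effect <- match.arg(effect)
  s <- switch(effect, birth = -1, death = 1, both = 0)
  g <- b - d
  m <- A + (N0 - A) * exp(g * t)
  v <- exp(2 * g * t) * (
    ((b + d + s * g) * A / (2 * g)) * (1 - exp(-2 * g * t)) +
      ((b + d) * (N0 - A) / g) * (1 - exp(-g * t))
  )
  list(mean = m, variance = v)
}

# Summary series built directly from a moment law (noiseless "data").
moments_as_summaries <- function(mom_fun, n0s, times, R) {
  do.call(rbind, lapply(n0s, function(n0) {
    mv <- mom_fun(n0, times)
    data.frame(n0 = n0, time_h = times, mean = mv$mean,
               variance = mv$variance, n_replicates = R)
  }))
}

# Simulated summary series for a preset-like design, optionally perturbed.
sim_summaries <- function(model, params, n0s, R, seed, horizon = 328,
                          interval = 4, noise = c(0, 0)) {
  design <- experiment_design(n0s, replicates = R, horizon = horizon,
                              sampling_interval = interval, seed = seed)
  ens <- simulate_ensemble(design, model, params)
  sm <- empirical_moments(as_count_table(ens))
  if (any(noise > 0)) {
    sm <- perturb_summaries(sm, noise[1], noise[2], seed = seed + 1)
  }
  sm
}

# A tiny well-level count table on a 3-point grid.
toy_count_table <- function() {
  data.frame(
    well_id = rep(c("w1", "w2", "w3"), each = 3),
    n0 = rep(c(4L, 4L, 2L), each = 3),
    time_h = rep(c(0, 4, 8), 3),
    count = c(4L, 5L, 7L, 4L, 4L, 6L, 2L, 3L, 3L),
    stringsAsFactors = FALSE
  )
}

quiet_fit <- function(...) suppressWarnings(allee_fit(...))
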