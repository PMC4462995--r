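# Independent oracles used across the suite.

# Direct summation of the forgetting-kernel failure law over a stored
# crossing-time history (the brute-force counterpart of the incremental
# accumulators).  Returns the raw ratio; clamping is applied by callers
# when comparing probabilities.
brute_failure_ratio <- function(times, tau_c, alpha) {
  m <- length(times)
  if (m < 2) return(0)
  k <- seq_len(m - 1)
  gaps <- diff(times)
  w <- exp(-alpha * (m - k + 1))
  sum((1 - gaps / tau_c) * w) / sum(w)
}

# Run register_crossing over a history and return the final accumulator
# ratio (raw) plus the per-crossing clamped probabilities.
incremental_failure_ratio <- function(times, tau_c, alpha) {
  spec <- neuron_spec(tau_c = tau_c, alpha = alpha)
  st <- impedance_state()
  for (t in times) {
    st <- register_crossing(st, t, spec)$state
    st$refractory_until <- NA_real_  # pure history bookkeeping
  }
  if (st$n_crossings < 2L || st$s_den <= 0) 0 else st$s_num / st$s_den
}

# Random strictly increasing crossing history.
random_history <- function(n, min_gap = 1, max_gap = 400) {
  cumsum(runif(n, min_gap, max_gap))
}

# Mean rate over several seeds for a network configuration.
seed_mean_rate <- function(seeds, ...) {
  mean(vapply(seeds,
              function(s) run_experiment(..., seed = s)$mean_rate,
              numeric(1)))
}
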