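#' Build the prototypical excitatory network topology
#'
#' Constructs the directed, weighted, delayed excitatory graph used in the
#' network simulations.  The base step assigns each neuron exactly one
#' post-synaptic and one pre-synaptic partner, i.e. a uniformly random
#' permutation without fixed points (a derangement, sampled by rejection).
#' Supplemental above-threshold connections (weight `j`) are then drawn
#' independently for every ordered pair not already connected and not a
#' self-pair, with probability `p_extra`; optional sub-threshold connections
#' with weight `j_sub` are drawn the same way with probability `p_sub`.
#' Delays are uniform on `delay_range` ms.  Each neuron receives a critical
#' frequency \eqn{f_C}: either one of two values with equal probability
#' (`fc_mode = "two_point"`), uniform between them (`"uniform"`), or a
#' user-supplied vector in Hz (`"custom"`).
#'
#' @param n Number of neurons (>= 2).
#' @param p_extra Probability of a supplemental above-threshold edge per
#'   ordered pair; the prototypical value is `0.1 / n`, which gives each
#'   neuron a second post-synaptic target with probability ~0.1.
#' @param fc_mode `"two_point"`, `"uniform"` or `"custom"`.
#' @param fc_values For `"two_point"` the two f_C values in Hz (defaults
#'   6.66 and 14.28 Hz, i.e. critical periods 150 and 70 ms); for
#'   `"uniform"` the range bounds in Hz.
#' @param fc_custom Numeric vector of length `n` of f_C values in Hz when
#'   `fc_mode = "custom"`.
#' @param p_sub Probability of a supplemental sub-threshold edge.
#' @param j_sub Weight of sub-threshold edges (dimensionless, < 1).
#' @param alpha Forgetting exponent assigned to every neuron.
#' @param delay_range Delay bounds in ms (default `c(6, 9.5)`).
#' @param j Weight of above-threshold edges (dimensionless, default 2).
#' @param tau_m Membrane time constant in ms for every neuron.
#' @param seed Optional integer seed.
#'
#' @return An object of class `network_topology`: a list with `n`, `edges`
#'   (data frame `pre`, `post`, `weight`, `delay_ms`; 1-based ids) and
#'   `neurons` (data frame `id`, `tau_c_ms`, `fc_hz`, `alpha`, `tau_m`).
#' @examples
#' topo <- build_topology(50, seed = 1)
#' topo
#' @export
build_topology <- function(n, p_extra = 0.1 / n,
                           fc_mode = c("two_point", "uniform", "custom"),
                           fc_values = c(6.66, 14.28), fc_custom = NULL,
                           p_sub = 0, j_sub = 0, alpha = 1.4,
                           delay_range = c(6, 9.5), j = 2, tau_m = 20,
                           seed = NULL) {
  if (!is.numeric(n) || length(n) != 1L || n < 2) stop("'n' must be >= 2")
  n <- as.integer(n)
  fc_mode <- match.arg(fc_mode)
  stopifnot(p_extra >= 0, p_extra <= 1, p_sub >= 0, p_sub <= 1)
  if (!is.null(seed)) set.seed(seed)

  # base step: uniform derangement by rejection
  repeat {
    post <- sample.int(n)
    if (!any(post == seq_len(n))) break
  }
  pre <- seq_len(n)
  base_key <- (pre - 1) * n + (post - 1)

  sample_pairs <- function(p, exclude_keys) {
    # independent Bernoulli over ordered non-self pairs not in exclude_keys,
    # realized as a binomial count plus uniform sampling of distinct pairs
    m_total <- as.numeric(n) * (n - 1) - length(exclude_keys)
    if (p <= 0 || m_total <= 0) return(cbind(integer(0), integer(0)))
    k <- rbinom(1, size = m_total, prob = p)
    if (k == 0) return(cbind(integer(0), integer(0)))
    chosen <- integer(0)
    while (length(chosen) < k) {
      idx <- sample.int(as.integer(n * (n - 1)), k - length(chosen),
                        replace = TRUE)
      # map index in 1..n(n-1) to an ordered pair (a, b), a != b
      a <- (idx - 1L) %/% (n - 1L) + 1L
      r <- (idx - 1L) %% (n - 1L) + 1L
      b <- ifelse(r >= a, r + 1L, r)
      key <- (a - 1) * n + (b - 1)
      ok <- !(key %in% exclude_keys) & !(key %in% chosen) & !duplicated(key)
      chosen <- c(chosen, key[ok])
    }
    chosen <- chosen[seq_len(k)]
    cbind(as.integer(chosen %/% n) + 1L, as.integer(chosen %% n) + 1L)
  }

  extra <- sample_pairs(p_extra, base_key)
  sub <- if (p_sub > 0)
    sample_pairs(p_sub, c(base_key, (extra[, 1] - 1) * n + (extra[, 2] - 1)))
  else cbind(integer(0), integer(0))

  edges <- data.frame(
    pre = c(pre, extra[, 1], sub[, 1]),
    post = c(post, extra[, 2], sub[, 2]),
    weight = c(rep(j, n + nrow(extra)), rep(j_sub, nrow(sub))))
  edges$delay_ms <- runif(nrow(edges), delay_range[1], delay_range[2])

  fc <- switch(fc_mode,
    two_point = sample(fc_values, n, replace = TRUE),
    uniform = runif(n, fc_values[1], fc_values[2]),
    custom = {
      if (is.null(fc_custom) || length(fc_custom) != n)
        stop("'fc_custom' must be a numeric vector of length n")
      fc_custom
    })
  # the two-point values are quoted as approximate frequencies of the round
  # critical periods 150 and 70 ms; use the exact periods in that mode
  tau_c <- if (fc_mode == "two_point")
    c(150, 70)[match(fc, fc_values)] else 1000 / fc

  neurons <- data.frame(id = seq_len(n), tau_c_ms = tau_c, fc_hz = fc,
                        alpha = alpha, tau_m = tau_m)
  structure(list(n = n, edges = edges, neurons = neurons,
                 params = list(p_extra = p_extra, fc_mode = fc_mode,
                               fc_values = fc_values, p_sub = p_sub,
                               j_sub = j_sub, j = j,
                               delay_range = delay_range)),
            class = "network_topology")
}

#' @export
print.network_topology <- function(x, ...) {
  above <- sum(x$edges$weight >= 1)
  cat(sprintf("Excitatory LIF network: %d neurons, %d edges (%d above-, %d sub-threshold)\n",
              x$n, nrow(x$edges), above, nrow(x$edges) - above))
  cat(sprintf("  f_C mode '%s'; alpha = %g; delays in [%g, %g] ms\n",
              x$params$fc_mode, x$neurons$alpha[1],
              x$params$delay_range[1], x$params$delay_range[2]))
  invisible(x)
}

#' @export
summary.network_topology <- function(object, ...) {
  deg_out <- tabulate(object$edges$pre[object$edges$weight >= 1], object$n)
  cat(sprintf("n = %d; mean above-threshold out-degree %.3f\n",
              object$n, mean(deg_out)))
  cat("f_C distribution (Hz):\n")
  print(summary(object$neurons$fc_hz))
  invisible(object)
}

#' Poisson-thinned initial stimulation schedule
#'
#' Generates the external stimulations that kick-start network activity:
#' per neuron, candidate times from a Poisson process at `rate` Hz on
#' `[0, horizon)` ms, each retained with survival probability
#' `exp(-T / survival_tau)` where `T` is the candidate time in ms.  After
#' the horizon the network is self-sustaining and no external input is
#' given.  The expected number of surviving stimulations per neuron is
#' `rate/1000 * survival_tau * (1 - exp(-horizon / survival_tau))`.
#'
#' @param n Number of neurons.
#' @param rate Candidate Poisson rate, Hz (default 50).
#' @param survival_tau Survival time constant, ms (default 200).
#' @param horizon Latest admitted stimulation time, ms (default 1000).
#' @param strength Stimulus strength (dimensionless, default 2:
#'   above threshold, matching the connection strength).
#' @param seed Optional integer seed.
#' @return A `stimulus_schedule`: data frame `neuron`, `time_ms`,
#'   `strength`, sorted by time.
#' @export
initial_stimulation_schedule <- function(n, rate = 50, survival_tau = 200,
                                         horizon = 1000, strength = 2,
                                         seed = NULL) {
  stopifnot(rate > 0, survival_tau > 0, horizon >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (horizon == 0)
    return(empty_schedule())
  k <- rpois(n, rate / 1000 * horizon)
  neuron <- rep.int(seq_len(n), k)
  times <- runif(sum(k), 0, horizon)
  keep <- runif(sum(k)) < exp(-times / survival_tau)
  sched <- data.frame(neuron = neuron[keep], time_ms = times[keep],
                      strength = strength)
  as_schedule(sched[order(sched$time_ms), ])
}

#' Spontaneous stimulation schedule
#'
#' Independent Bernoulli stimulation per neuron and integration step with
#' probability `per_step_probability`; the default `5e-5` at `dt = 0.05` ms
#' yields on average one spontaneous stimulation per neuron per second.
#' Realized per neuron as a binomial count of steps followed by uniform
#' sampling of distinct steps, which is distributionally identical to the
#' per-step draws.
#'
#' @param n Number of neurons.
#' @param per_step_probability Probability per step, in \[0, 1\].
#' @param dt Integration step, ms.
#' @param duration Schedule duration, ms.
#' @param strength Stimulus strength (dimensionless, default 2).
#' @param seed Optional integer seed.
#' @return A `stimulus_schedule`.
#' @export
spontaneous_schedule <- function(n, per_step_probability = 5e-5, dt = 0.05,
                                 duration = 60000, strength = 2,
                                 seed = NULL) {
  stopifnot(per_step_probability >= 0, per_step_probability <= 1,
            dt > 0, duration >= 0)
  if (!is.null(seed)) set.seed(seed)
  n_steps <- as.integer(round(duration / dt))
  if (per_step_probability == 0 || n_steps == 0)
    return(empty_schedule())
  k <- rbinom(n, n_steps, per_step_probability)
  neuron <- rep.int(seq_len(n), k)
  steps <- unlist(lapply(k, function(ki) sample.int(n_steps, ki) - 1L),
                  use.names = FALSE)
  sched <- data.frame(neuron = neuron, time_ms = steps * dt,
                      strength = strength)
  as_schedule(sched[order(sched$time_ms), ])
}

empty_schedule <- function() {
  as_schedule(data.frame(neuron = integer(0), time_ms = numeric(0),
                         strength = numeric(0)))
}

as_schedule <- function(df) {
  stopifnot(all(c("neuron", "time_ms", "strength") %in% names(df)))
  if (any(df$time_ms < 0)) stop("schedule times must be non-negative")
  rownames(df) <- NULL
  class(df) <- c("stimulus_schedule", "data.frame")
  df
}
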