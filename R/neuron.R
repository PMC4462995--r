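#' Static parameters of an impedance LIF neuron
#'
#' Bundles the per-neuron constants of the leaky integrate-and-fire model
#' with stochastic response failures.  Voltages are expressed in the
#' rescaled dimensionless units in which the firing threshold is 1 and the
#' stable (resting) potential is 0.  The map back to membrane potential is
#' \eqn{V' = (V_{threshold} - V_{stable}) V + V_{stable}} with
#' \eqn{V_{stable} = -70} mV and \eqn{V_{threshold} = -54} mV, so a
#' dimensionless synaptic weight \eqn{J} corresponds to \eqn{16 J} mV.
#'
#' @param tau_m Membrane time constant, ms.
#' @param v_threshold Firing threshold (dimensionless; 1 after rescaling).
#' @param v_stable Stable potential (dimensionless; 0 after rescaling).
#' @param v_reset Voltage applied at the end of the refractory period after
#'   an evoked spike (dimensionless).
#' @param v_fail Voltage set immediately after a response failure, with no
#'   refractory period (dimensionless).
#' @param t_refractory Absolute refractory period after an evoked spike, ms.
#'   While refractory the neuron is inactive and discards arriving inputs.
#' @param tau_c Critical period \eqn{\tau_C = 1/f_C}, ms.  Sustained drive
#'   with inter-crossing intervals below \eqn{\tau_C} produces response
#'   failures.
#' @param alpha Forgetting exponent \eqn{\alpha \ge 0}: decay rate of the
#'   exponential weighting of past inter-crossing intervals in the failure
#'   probability.  Larger \eqn{\alpha} means shorter memory.
#'
#' @return An object of class `neuron_spec`.
#' @examples
#' spec <- neuron_spec(tau_c = 150, alpha = 1.4)
#' spec
#' @export
neuron_spec <- function(tau_m = 20, v_threshold = 1, v_stable = 0,
                        v_reset = -0.5, v_fail = 0.2, t_refractory = 2,
                        tau_c = 150, alpha = 1.4) {
  stopifnot(is.numeric(tau_m), length(tau_m) == 1L,
            is.numeric(tau_c), length(tau_c) == 1L,
            is.numeric(alpha), length(alpha) == 1L)
  if (tau_m <= 0) stop("'tau_m' must be positive")
  if (tau_c <= 0) stop("'tau_c' must be positive")
  if (alpha < 0) stop("'alpha' must be non-negative")
  if (!(v_reset < v_fail && v_fail < v_threshold))
    stop("'v_reset' < 'v_fail' < 'v_threshold' is required")
  if (t_refractory < 0) stop("'t_refractory' must be non-negative")
  structure(list(tau_m = tau_m, v_threshold = v_threshold,
                 v_stable = v_stable, v_reset = v_reset, v_fail = v_fail,
                 t_refractory = t_refractory, tau_c = tau_c, alpha = alpha),
            class = "neuron_spec")
}

#' @export
print.neuron_spec <- function(x, ...) {
  cat("Impedance LIF neuron\n")
  cat(sprintf("  tau_m = %g ms, refractory = %g ms\n", x$tau_m, x$t_refractory))
  cat(sprintf("  thresholds: v_threshold = %g, v_reset = %g, v_fail = %g\n",
              x$v_threshold, x$v_reset, x$v_fail))
  cat(sprintf("  critical period tau_c = %g ms (f_c = %.3g Hz), alpha = %g\n",
              x$tau_c, 1000 / x$tau_c, x$alpha))
  invisible(x)
}

#' Dynamic state of an impedance neuron
#'
#' Holds the voltage and the failure-history accumulators that realize the
#' forgetting-kernel failure probability incrementally.  `s_num` and `s_den`
#' are the exponentially decayed weighted sum of interval shortfall terms
#' \eqn{(1 - \Delta t_k / \tau_C)} and the matching decayed weight sum, so
#' that `s_num / s_den` reproduces the direct summation over the stored
#' crossing history to machine precision.
#'
#' @param v Initial voltage (dimensionless).
#' @return An object of class `impedance_state`.
#' @seealso [register_crossing()], [failure_probability()]
#' @export
impedance_state <- function(v = 0.5) {
  structure(list(v = v, refractory_until = NA_real_, n_crossings = 0L,
                 last_crossing_time = NA_real_, s_num = 0, s_den = 0),
            class = "impedance_state")
}

#' One Euler leak step of the membrane voltage
#'
#' Applies a single forward-Euler step of the leak equation
#' \eqn{dV/dt = -V/\tau_m} with no input: returns
#' `v - (v / tau_m) * dt`.  Vectorized over `v`.
#'
#' @param v Voltage (dimensionless), possibly a vector.
#' @param dt Integration time step, ms (default 0.05).
#' @param tau_m Membrane time constant, ms.
#' @return The voltage after one step.
#' @examples
#' euler_decay_step(0.5, 0.05, 20)  # 0.49875
#' @export
euler_decay_step <- function(v, dt = 0.05, tau_m = 20) {
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
    stop("'dt' must be a positive number")
  if (!is.numeric(tau_m) || length(tau_m) != 1L || tau_m <= 0)
    stop("'tau_m' must be a positive number")
  v - (v / tau_m) * dt
}

#' Response-failure probability from the stored crossing history
#'
#' Returns the clamped ratio of the history accumulators,
#' `clamp(s_num / s_den, 0, 1)`, which equals the forgetting-kernel weighted
#' mean of past interval shortfalls \eqn{(1 - \Delta t_k/\tau_C)}.  With
#' fewer than two crossings on record no interval is defined and the
#' probability is 0 (the initial condition of the model).  Clamping is
#' applied to the final ratio, not per term, so that for strictly periodic
#' histories with interval \eqn{\tau < \tau_C} the result is exactly
#' \eqn{(\tau_C - \tau)/\tau_C}.
#'
#' @param state An [impedance_state()].
#' @return A probability in \[0, 1\].
#' @export
failure_probability <- function(state) {
  stopifnot(inherits(state, "impedance_state"))
  if (state$n_crossings < 2L || state$s_den <= 0) return(0)
  min(max(state$s_num / state$s_den, 0), 1)
}

#' Register a threshold crossing and draw its outcome
#'
#' Appends the crossing to the history, evaluates the failure probability
#' over all completed inter-crossing intervals (including the one ending at
#' this crossing, which carries the largest kernel weight), draws one
#' uniform variate, and resolves the crossing into an evoked spike or a
#' response failure.  The crossing enters the history whatever the outcome
#' (the failure law is indexed by threshold crossings, not by spikes): both
#' accumulators are decayed by \eqn{e^{-\alpha}} and the newly completed
#' interval contributes a term \eqn{(1 - \Delta t/\tau_C) e^{-2\alpha}} with
#' weight \eqn{e^{-2\alpha}}.  The very first crossing has no interval on
#' record and always evokes a spike (the model's initial condition).
#'
#' On a failure the voltage is set to `spec$v_fail` and the neuron remains
#' immediately responsive.  On a spike the neuron becomes refractory until
#' `t + spec$t_refractory` and the voltage is reset to `spec$v_reset`,
#' taking effect at the refractory end.
#'
#' @param state An [impedance_state()].
#' @param t Time of the crossing, ms; must exceed the last crossing time.
#' @param spec A [neuron_spec()].
#' @param extra_failure_c Additional baseline failure probability `C`; the
#'   effective probability is `C + (1 - C) * p`.
#' @return A list with elements `state` (updated), `outcome` (`"spike"` or
#'   `"failure"`) and `p_fail` (the effective probability used).
#' @examples
#' set.seed(1)
#' st <- impedance_state()
#' out <- register_crossing(st, t = 10, neuron_spec())
#' out$outcome  # the first crossing always spikes
#' @export
register_crossing <- function(state, t, spec, extra_failure_c = 0) {
  stopifnot(inherits(state, "impedance_state"), inherits(spec, "neuron_spec"))
  if (!is.na(state$refractory_until) && t < state$refractory_until)
    stop("crossing registered during the refractory period")
  if (!is.na(state$last_crossing_time) && t <= state$last_crossing_time)
    stop("crossing time must exceed the last crossing time")

  ea <- exp(-spec$alpha)
  if (state$n_crossings >= 1L) {
    gap <- t - state$last_crossing_time
    state$s_num <- ea * state$s_num + (1 - gap / spec$tau_c) * ea^2
    state$s_den <- ea * state$s_den + ea^2
  }
  state$n_crossings <- state$n_crossings + 1L
  state$last_crossing_time <- t

  p <- failure_probability(state)
  p <- extra_failure_c + (1 - extra_failure_c) * p
  u <- runif(1)

  if (u < p) {
    state$v <- spec$v_fail
    state$refractory_until <- NA_real_
    list(state = state, outcome = "failure", p_fail = p)
  } else {
    state$v <- spec$v_reset
    state$refractory_until <- t + spec$t_refractory
    list(state = state, outcome = "spike", p_fail = p)
  }
}

#' Drive a single impedance neuron with suprathreshold stimuli
#'
#' Applies a sequence of suprathreshold stimulation times to one neuron:
#' every stimulus arriving outside the refractory period produces a
#' threshold crossing, which is resolved into a spike or a response failure
#' by the forgetting-kernel law.  Stimuli arriving while the neuron is
#' refractory are discarded.  This is the single-neuron analogue of the
#' network engine, used for stimulation protocols and failure statistics.
#'
#' @param spec A [neuron_spec()].
#' @param times Stimulation times, ms, strictly increasing; or a
#'   [make_stimulus_train()] object.
#' @param extra_failure_c Additional baseline failure probability.
#' @param seed Optional integer seed (`set.seed()` is called when given).
#' @return A list of class `neuron_drive` with elements `times` (accepted
#'   stimulation times), `outcomes` (1 = evoked spike, 0 = failure),
#'   `p_fail` (per-crossing effective probability), `spike_times`,
#'   `discarded` (stimuli falling into a refractory period) and `spec`.
#' @examples
#' d <- drive_neuron(neuron_spec(tau_c = 150), times = seq(50, 5000, by = 50),
#'                   seed = 1)
#' mean(d$outcomes == 0)  # failure fraction near (150 - 50)/150
#' @export
drive_neuron <- function(spec, times, extra_failure_c = 0, seed = NULL) {
  stopifnot(inherits(spec, "neuron_spec"))
  if (inherits(times, "stimulus_train")) times <- times$times
  if (is.unsorted(times, strictly = TRUE))
    stop("'times' must be strictly increasing")
  if (!is.null(seed)) set.seed(seed)

  n <- length(times)
  outcomes <- integer(n)
  pfs <- numeric(n)
  keep <- logical(n)
  ea <- exp(-spec$alpha)
  ea2 <- ea * ea
  s_num <- 0; s_den <- 0
  ncross <- 0L
  last_t <- NA_real_
  refr_until <- -Inf

  for (i in seq_len(n)) {
    t <- times[i]
    if (t < refr_until) next  # discarded during refractory
    keep[i] <- TRUE
    if (ncross >= 1L) {
      gap <- t - last_t
      s_num <- ea * s_num + (1 - gap / spec$tau_c) * ea2
      s_den <- ea * s_den + ea2
    }
    ncross <- ncross + 1L
    last_t <- t
    p <- if (ncross >= 2L && s_den > 0) min(max(s_num / s_den, 0), 1) else 0
    p <- extra_failure_c + (1 - extra_failure_c) * p
    u <- runif(1)
    pfs[i] <- p
    if (u < p) {
      outcomes[i] <- 0L
    } else {
      outcomes[i] <- 1L
      refr_until <- t + spec$t_refractory
    }
  }

  structure(list(times = times[keep], outcomes = outcomes[keep],
                 p_fail = pfs[keep],
                 spike_times = times[keep][outcomes[keep] == 1L],
                 discarded = times[!keep], spec = spec),
            class = "neuron_drive")
}

#' @export
print.neuron_drive <- function(x, ...) {
  n <- length(x$outcomes)
  cat(sprintf("Single-neuron drive: %d crossings, %d spikes, %d failures\n",
              n, sum(x$outcomes == 1L), sum(x$outcomes == 0L)))
  if (n > 1L) {
    isi <- diff(x$spike_times)
    cat(sprintf("  failure fraction %.3f, mean ISI %.1f ms (tau_c = %g ms)\n",
                mean(x$outcomes == 0L), mean(isi), x$spec$tau_c))
  }
  invisible(x)
}
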