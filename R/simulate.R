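#' Simulate an impedance LIF network
#'
#' Time-stepped simulation of a [build_topology()] network under external
#' stimulation.  Synaptic and external inputs are delivered as voltage
#' impulses (`v <- v + J`); within each integration step all inputs due are
#' accumulated first, the Euler leak factor `1 - dt/tau_m` is applied once,
#' and the threshold is tested once, so simultaneous arrivals sum before a
#' single crossing test.  A threshold crossing is resolved into an evoked
#' spike or a response failure with effective probability
#' `C + (1 - C) * P_fail`, where `P_fail` is the forgetting-kernel law of
#' [failure_probability()].  Spikes enqueue deliveries to all post-synaptic
#' targets after the edge delay (rounded to integer steps); refractory
#' neurons discard arriving inputs.  The initial voltage is 0.5 for all
#' neurons.  One uniform variate is drawn per crossing, in ascending
#' neuron-index order within a step, so runs are reproducible from the
#' seed alone.
#'
#' @param topology A [build_topology()] object.
#' @param schedules A `stimulus_schedule` or list of them (external
#'   stimulation events).
#' @param duration_ms Simulated duration, ms.
#' @param dt Integration step, ms (default 0.05).
#' @param extra_failure_c Additional baseline failure probability `C`
#'   applied at every crossing (default 0).
#' @param seed Optional integer seed.
#' @return An `event_log`: data frame `time_ms`, `neuron` (1-based),
#'   `kind` (factor: `stimulus`, `crossing`, `spike`, `failure`), time
#'   ordered, with attributes `n_neurons`, `duration_ms`, `dt`.  Every
#'   spike and failure row coincides with a crossing row.
#' @examples
#' topo <- build_topology(20, seed = 1)
#' sched <- initial_stimulation_schedule(20, horizon = 200)
#' log <- simulate_network(topo, sched, duration_ms = 2000, seed = 1)
#' table(log$kind)
#' @export
simulate_network <- function(topology, schedules = list(),
                             duration_ms = 60000, dt = 0.05,
                             extra_failure_c = 0, seed = NULL) {
  stopifnot(inherits(topology, "network_topology"))
  if (!is.numeric(duration_ms) || duration_ms <= 0)
    stop("'duration_ms' must be positive")
  if (!is.numeric(dt) || dt <= 0) stop("'dt' must be positive")
  stopifnot(extra_failure_c >= 0, extra_failure_c <= 1)
  if (!is.null(seed)) set.seed(seed)

  if (inherits(schedules, "stimulus_schedule")) schedules <- list(schedules)
  stim <- if (length(schedules)) do.call(rbind, lapply(schedules, as.data.frame))
          else data.frame(neuron = integer(0), time_ms = numeric(0),
                          strength = numeric(0))

  n_steps <- as.integer(round(duration_ms / dt))
  edges <- topology$edges
  if (any(edges$delay_ms < dt))
    warning("edge delays shorter than dt are rounded up to one step")
  delay_steps <- pmax(1L, as.integer(round(edges$delay_ms / dt)))

  stim_step <- as.integer(round(stim$time_ms / dt))
  keep <- stim_step >= 0L & stim_step < n_steps
  stim <- stim[keep, , drop = FALSE]
  stim_step <- stim_step[keep]
  ord <- order(stim_step, stim$neuron)

  nr <- topology$neurons
  spec <- neuron_spec()  # shared voltage constants of the rescaled model
  res <- .sim_core(topology$n,
                   as.integer(edges$pre - 1L), as.integer(edges$post - 1L),
                   as.numeric(edges$weight), delay_steps,
                   as.numeric(nr$tau_m), as.numeric(nr$tau_c_ms),
                   as.numeric(nr$alpha),
                   stim_step[ord], as.integer(stim$neuron[ord] - 1L),
                   as.numeric(stim$strength[ord]),
                   n_steps, dt, extra_failure_c,
                   spec$v_threshold, spec$v_reset, spec$v_fail,
                   as.integer(round(spec$t_refractory / dt)), 0.5)

  kinds <- c("stimulus", "crossing", "spike", "failure")
  log <- data.frame(time_ms = res$step * dt,
                    neuron = res$neuron + 1L,
                    kind = factor(kinds[res$kind + 1L], levels = kinds))
  structure(log, class = c("event_log", "data.frame"),
            n_neurons = topology$n, duration_ms = duration_ms, dt = dt)
}

#' @export
print.event_log <- function(x, ...) {
  cat(sprintf("Event log: %d neurons, %g ms simulated\n",
              attr(x, "n_neurons"), attr(x, "duration_ms")))
  print(table(x$kind))
  invisible(x)
}

#' Per-neuron firing-rate histogram
#'
#' Computes per-neuron firing rates as the number of evoked spikes inside
#' the analysis window divided by the window length, and bins them at
#' `bin` Hz (left-closed bins).  The default window, 4 to 59 s, skips the
#' initialization transient and spans 55 s.
#'
#' @param log An `event_log` from [simulate_network()].
#' @param n Number of neurons (defaults to the log attribute).
#' @param window Analysis window `c(start, end)` in ms; must lie within the
#'   simulated duration.
#' @param bin Bin width, Hz (default 0.5).
#' @return An object of class `rate_histogram`: list with `bin_low_hz`,
#'   `counts` (summing to `n`), `rates` (per neuron, Hz), `mean_rate`,
#'   `window_ms`, `bin_hz`.
#' @export
firing_rate_histogram <- function(log, n = attr(log, "n_neurons"),
                                  window = c(4000, 59000), bin = 0.5) {
  stopifnot(inherits(log, "event_log") || is.data.frame(log))
  dur <- attr(log, "duration_ms")
  if (!is.null(dur) && window[2] > dur)
    stop("analysis window extends beyond the simulated duration")
  sp <- log$neuron[log$kind == "spike" &
                   log$time_ms >= window[1] & log$time_ms < window[2]]
  counts_per_neuron <- tabulate(sp, n)
  rates <- counts_per_neuron / ((window[2] - window[1]) / 1000)
  top <- if (length(rates) && max(rates) > 0) ceiling(max(rates) / bin) else 1
  bin_low <- (seq_len(top + 1) - 1) * bin
  counts <- tabulate(pmin(floor(rates / bin), top) + 1L, top + 1L)
  structure(list(bin_low_hz = bin_low, counts = counts, rates = rates,
                 mean_rate = mean(rates), window_ms = window, bin_hz = bin),
            class = "rate_histogram")
}

#' @export
print.rate_histogram <- function(x, ...) {
  cat(sprintf("Firing-rate histogram over [%g, %g] s: mean %.3f Hz, %d neurons\n",
              x$window_ms[1] / 1000, x$window_ms[2] / 1000,
              x$mean_rate, sum(x$counts)))
  invisible(x)
}

#' @export
plot.rate_histogram <- function(x, xlab = "firing rate (Hz)",
                                ylab = "neurons", ...) {
  barplot(x$counts, names.arg = x$bin_low_hz, space = 0,
          xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Run a complete network experiment
#'
#' Convenience pipeline: build the topology, generate the Poisson-thinned
#' initial stimulation (and an optional spontaneous schedule), simulate,
#' and summarize per-neuron firing rates.  All randomness derives from the
#' single `seed`.
#'
#' @param n Network size.
#' @param fc_mode,fc_values,fc_custom,alpha,p_extra,p_sub,j_sub See
#'   [build_topology()].
#' @param extra_failure_c Additional baseline failure probability `C`.
#' @param spontaneous_p Per-step spontaneous stimulation probability
#'   (0 disables; `5e-5` gives ~1 Hz per neuron at the default step).
#' @param duration_ms,dt See [simulate_network()].
#' @param rate_window Analysis window in ms; `NULL` uses 4 s to 1 s before
#'   the end (the standard 4-59 s window at the default duration).
#' @param seed Integer seed for the whole run.
#' @return An object of class `impedance_run`: list with `topology`,
#'   `events`, `histogram`, `mean_rate`, `params`.
#' @examples
#' run <- run_experiment(n = 100, duration_ms = 5000, seed = 1)
#' run$mean_rate
#' @export
run_experiment <- function(n = 2000, fc_mode = "two_point",
                           fc_values = c(6.66, 14.28), fc_custom = NULL,
                           alpha = 1.4, p_extra = 0.1 / n, p_sub = 0,
                           j_sub = 0, extra_failure_c = 0,
                           spontaneous_p = 0, duration_ms = 60000,
                           dt = 0.05, rate_window = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  topo <- build_topology(n, p_extra = p_extra, fc_mode = fc_mode,
                         fc_values = fc_values, fc_custom = fc_custom,
                         p_sub = p_sub, j_sub = j_sub, alpha = alpha)
  scheds <- list(initial_stimulation_schedule(n))
  if (spontaneous_p > 0)
    scheds <- c(scheds, list(spontaneous_schedule(
      n, spontaneous_p, dt = dt, duration = duration_ms)))
  log <- simulate_network(topo, scheds, duration_ms = duration_ms, dt = dt,
                          extra_failure_c = extra_failure_c)
  if (is.null(rate_window)) rate_window <- c(4000, duration_ms - 1000)
  hist <- firing_rate_histogram(log, n, window = rate_window)
  structure(list(topology = topo, events = log, histogram = hist,
                 mean_rate = hist$mean_rate,
                 params = list(n = n, fc_mode = fc_mode,
                               fc_values = fc_values, alpha = alpha,
                               p_extra = p_extra, p_sub = p_sub,
                               j_sub = j_sub,
                               extra_failure_c = extra_failure_c,
                               spontaneous_p = spontaneous_p,
                               duration_ms = duration_ms, dt = dt,
                               rate_window = rate_window, seed = seed)),
            class = "impedance_run")
}

#' @export
print.impedance_run <- function(x, ...) {
  p <- x$params
  cat(sprintf("Impedance network run: n = %d, f_C mode '%s', alpha = %g\n",
              p$n, p$fc_mode, p$alpha))
  cat(sprintf("  mean firing rate %.3f Hz over [%g, %g] s (lowest f_C %.3g Hz)\n",
              x$mean_rate, p$rate_window[1] / 1000, p$rate_window[2] / 1000,
              min(x$topology$neurons$fc_hz)))
  invisible(x)
}

#' @export
plot.impedance_run <- function(x, ...) {
  old <- par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(par(old))
  fc <- x$topology$neurons$fc_hz
  b <- x$histogram$bin_hz
  top <- max(ceiling(max(fc) / b), length(x$histogram$counts))
  fc_counts <- tabulate(pmin(floor(fc / b), top - 1L) + 1L, top)
  barplot(fc_counts, names.arg = (seq_len(top) - 1) * b, space = 0,
          main = "critical frequencies", xlab = "f_C (Hz)", ylab = "neurons")
  plot(x$histogram, main = sprintf("firing rates (mean %.2f Hz)",
                                   x$mean_rate))
  invisible(x)
}
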