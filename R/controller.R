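#' Phenomenological latency responder
#'
#' A configurable stand-in for a live neuron in closed-loop latency
#' experiments.  It is deliberately phenomenological: a monotone stationary
#' latency map \eqn{L^*(\tau)} (latency decreasing in the stimulation lag),
#' exponential relaxation of a slow internal latency state toward
#' \eqn{L^*} at `relaxation_rate` per stimulation, a small fast component
#' that reflects the immediate sensitivity of the latency to the current
#' lag (ultra-fast plasticity), Gaussian jitter on the emitted latency,
#' and, when driven faster than the critical frequency, intermittent-phase
#' response failures at the periodic-limit rate
#' \eqn{(\tau_C - \tau)/\tau_C}.
#'
#' The stationary map is
#' \deqn{L^*(\tau) = L_0 + (L_C - L_0) e^{-(\tau - \tau_C)/s}, \quad
#'       \tau \ge \tau_C,}
#' saturating at \eqn{L_C} for \eqn{\tau < \tau_C}.  With the default
#' calibration (`l_initial = 1` ms, `l_c = 11` ms, `tau_c = 150` ms,
#' `length_scale = 52.6` ms) the lag whose stationary latency equals 5 ms
#' is 198.2 ms, and under a fixed lag the residual to the stationary
#' latency decays at `2e-4` per stimulation.
#'
#' @param l_initial Latency at very long lags (fully recovered neuron), ms.
#' @param l_c Saturated latency at the intermittent phase, ms.
#' @param tau_c Critical period, ms.
#' @param length_scale Lag scale of the stationary map, ms.
#' @param relaxation_rate Per-stimulation relaxation rate of the slow
#'   latency state toward the stationary map.
#' @param fast_fraction Weight of the instantaneous stationary latency in
#'   the emitted value (the ultra-fast component).
#' @param jitter_sd Gaussian jitter of the emitted latency, ms
#'   (default 0.014 ms = 14 us).
#' @return An object of class `latency_responder`.
#' @seealso [respond()], [stationary_latency()], [adaptive_latency_controller()]
#' @export
synthetic_latency_responder <- function(l_initial = 1, l_c = 11,
                                        tau_c = 150, length_scale = 52.6,
                                        relaxation_rate = 2e-4,
                                        fast_fraction = 0.05,
                                        jitter_sd = 0.014) {
  stopifnot(l_c > l_initial, tau_c > 0, length_scale > 0,
            relaxation_rate > 0, relaxation_rate <= 1,
            fast_fraction >= 0, fast_fraction < 1, jitter_sd >= 0)
  st <- new.env(parent = emptyenv())
  st$l_slow <- l_initial
  structure(list(l_initial = l_initial, l_c = l_c, tau_c = tau_c,
                 length_scale = length_scale,
                 relaxation_rate = relaxation_rate,
                 fast_fraction = fast_fraction, jitter_sd = jitter_sd,
                 state = st),
            class = "latency_responder")
}

#' @export
print.latency_responder <- function(x, ...) {
  cat(sprintf("Phenomenological latency responder: L* in [%g, %g] ms, tau_c = %g ms\n",
              x$l_initial, x$l_c, x$tau_c))
  cat(sprintf("  relaxation %g/stim, fast fraction %g, jitter %g ms; current slow state %.3f ms\n",
              x$relaxation_rate, x$fast_fraction, x$jitter_sd, x$state$l_slow))
  invisible(x)
}

#' Stationary latency map of a responder
#'
#' @param responder A [synthetic_latency_responder()].
#' @param tau Stimulation lag(s), ms.
#' @return Stationary latency, ms (saturates at `l_c` below `tau_c`).
#' @export
stationary_latency <- function(responder, tau) {
  stopifnot(inherits(responder, "latency_responder"))
  ifelse(tau >= responder$tau_c,
         responder$l_initial + (responder$l_c - responder$l_initial) *
           exp(-(tau - responder$tau_c) / responder$length_scale),
         responder$l_c)
}

#' Lag whose stationary latency equals a target
#'
#' Inverse of [stationary_latency()] on its decreasing branch; the fixed
#' point of the closed loop that stabilizes the latency at `l_target`.
#'
#' @param responder A [synthetic_latency_responder()].
#' @param l_target Target latency, ms, in `(l_initial, l_c)`.
#' @return The stationary lag, ms.
#' @examples
#' stationary_lag(synthetic_latency_responder(), 5)  # 198.2 ms
#' @export
stationary_lag <- function(responder, l_target) {
  stopifnot(inherits(responder, "latency_responder"),
            l_target > responder$l_initial, l_target < responder$l_c)
  responder$tau_c + responder$length_scale *
    log((responder$l_c - responder$l_initial) /
        (l_target - responder$l_initial))
}

#' Stimulate a responder once
#'
#' Advances the responder's slow latency state by one stimulation with lag
#' `tau` and returns the emitted latency, or `NA` on a response failure
#' (possible only when `tau < tau_c`, with the periodic-limit probability).
#' The slow state advances on failures too: the stimulation arrived.
#'
#' @param responder A [synthetic_latency_responder()] (stateful; modified
#'   in place).
#' @param tau Lag since the previous stimulation, ms.
#' @return Latency in ms, or `NA_real_` for a failure.
#' @export
respond <- function(responder, tau) {
  stopifnot(inherits(responder, "latency_responder"), tau > 0)
  g <- stationary_latency(responder, tau)
  st <- responder$state
  st$l_slow <- st$l_slow + responder$relaxation_rate * (g - st$l_slow)
  if (tau < responder$tau_c &&
      runif(1) < (responder$tau_c - tau) / responder$tau_c)
    return(NA_real_)
  (1 - responder$fast_fraction) * st$l_slow +
    responder$fast_fraction * g + rnorm(1, 0, responder$jitter_sd)
}

#' Closed-loop latency stabilization
#'
#' Real-time adaptive stabilization of the response latency around a
#' target `l_target`: after each stimulation the next lag is shortened by
#' `delta` when the observed latency is below target, lengthened by
#' `delta` when above, and left unchanged when exactly on target.  A
#' response failure (no latency observed) is treated as an over-long
#' latency and lengthens the lag; this is the natural reading since
#' failures arise from over-driving.  Lags are clamped below at
#' `tau_floor` (with a one-time warning).
#'
#' @param l_target Target latency `L_ST`, ms.
#' @param delta Lag adjustment step, ms (>= 0).
#' @param tau_init Initial lag, ms.
#' @param responder A [synthetic_latency_responder()], or a function
#'   `function(tau)` returning a latency in ms (or `NA` for a failure).
#' @param steps Number of stimulations.
#' @param tau_floor Smallest admissible lag, ms.
#' @param seed Optional integer seed.
#' @return An object of class `latency_control`: data frame `stim_index`,
#'   `tau_ms` (lag used), `latency_ms` (`NA` on failure), plus parameter
#'   attributes.
#' @examples
#' r <- synthetic_latency_responder()
#' ctl <- adaptive_latency_controller(5, 20, 500, r, steps = 2000, seed = 1)
#' ctl
#' @export
adaptive_latency_controller <- function(l_target, delta, tau_init,
                                        responder, steps,
                                        tau_floor = 1, seed = NULL) {
  stopifnot(delta >= 0, tau_init > 0, steps >= 1, tau_floor > 0)
  if (!is.null(seed)) set.seed(seed)
  step_fn <- if (inherits(responder, "latency_responder"))
    function(tau) respond(responder, tau) else match.fun(responder)

  tau <- numeric(steps)
  lat <- numeric(steps)
  cur <- tau_init
  clamped <- FALSE
  for (i in seq_len(steps)) {
    tau[i] <- cur
    l <- step_fn(cur)
    lat[i] <- l
    if (is.na(l) || l > l_target) {
      cur <- cur + delta
    } else if (l < l_target) {
      cur <- cur - delta
    }
    if (cur < tau_floor) {
      cur <- tau_floor
      if (!clamped) {
        warning("lag clamped at the configured floor")
        clamped <- TRUE
      }
    }
  }
  structure(data.frame(stim_index = seq_len(steps), tau_ms = tau,
                       latency_ms = lat),
            class = c("latency_control", "data.frame"),
            l_target = l_target, delta = delta, tau_floor = tau_floor)
}

#' @export
print.latency_control <- function(x, ...) {
  n <- nrow(x)
  last <- x[seq(max(1, n - 999), n), ]
  cat(sprintf("Closed-loop latency control: %d stimulations, target %g ms\n",
              n, attr(x, "l_target")))
  cat(sprintf("  last 1000: mean lag %.1f ms, mean latency %.3f ms, %d failures\n",
              mean(last$tau_ms), mean(last$latency_ms, na.rm = TRUE),
              sum(is.na(last$latency_ms))))
  invisible(x)
}

#' @export
plot.latency_control <- function(x, ...) {
  old <- par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(par(old))
  plot(x$stim_index, x$tau_ms, type = "l", xlab = "", ylab = "lag (ms)", ...)
  plot(x$stim_index, x$latency_ms, pch = ".", xlab = "stimulation",
       ylab = "latency (ms)", ...)
  abline(h = attr(x, "l_target"), lty = 2)
  invisible(x)
}
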