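#' Sub-sample threshold-crossing time by linear interpolation
#'
#' Recovers a spike's threshold-crossing time below the sampling
#' resolution of the recording device.  Given the two samples bracketing
#' the crossing, `(t1, v1)` and `(t1 + interval, v2)`, the crossing time
#' is the linear interpolation
#' `t1 + (v_threshold - v1) / (v2 - v1) * interval`.  Both downward
#' (`v1 >= v_threshold > v2`) and upward crossings are handled; the
#' samples must bracket the threshold.
#'
#' @param t1 Time of the first sample, ms.
#' @param v1,v2 Voltages of the two consecutive samples, uV.
#' @param v_threshold Detection threshold, uV.
#' @param sample_interval_us Sampling interval, us (default 20, i.e. a
#'   50 kHz recording).
#' @return Crossing time in ms.
#' @examples
#' interpolate_crossing_time(0, -10, -30, -25)  # 0.015 ms = 15 us
#' @export
interpolate_crossing_time <- function(t1, v1, v2, v_threshold,
                                      sample_interval_us = 20) {
  if (v1 == v2) stop("degenerate samples: v1 == v2")
  if ((v1 - v_threshold) * (v2 - v_threshold) > 0)
    stop("samples do not bracket the threshold")
  t1 + (v_threshold - v1) / (v2 - v1) * sample_interval_us / 1000
}

#' Timing uncertainty induced by electrode noise
#'
#' Linear error propagation through the crossing interpolation: voltage
#' noise of standard deviation `sigma_v` on samples with local slope
#' `delta_v_per_sample` per sampling interval translates into a
#' crossing-time uncertainty of
#' `sample_interval * sigma_v / delta_v_per_sample`.
#'
#' @param sigma_v Electrode noise standard deviation, uV.
#' @param delta_v_per_sample Voltage change between consecutive samples in
#'   the crossing region, uV.
#' @param sample_interval_us Sampling interval, us (default 20).
#' @return Timing standard deviation, us.
#' @examples
#' propagate_threshold_noise(2.14, 15)  # 2.85 us
#' @export
propagate_threshold_noise <- function(sigma_v, delta_v_per_sample,
                                      sample_interval_us = 20) {
  if (delta_v_per_sample <= 0)
    stop("'delta_v_per_sample' must be positive")
  stopifnot(sigma_v >= 0)
  sample_interval_us * sigma_v / delta_v_per_sample
}

#' Rolling standard deviation of a latency trace
#'
#' Trailing-window standard deviation of response latencies, with failures
#' (`NA`) excluded within each window.  Uses the population convention
#' (divide by the number of values); at the customary window of 1000 the
#' difference from the sample convention is far below reported precision.
#'
#' @param latencies Latency sequence, ms (`NA` marks failures).
#' @param window Window length in stimulations (>= 2).
#' @return Numeric vector of length `length(latencies) - window + 1`
#'   (empty, with a warning, when the window exceeds the trace).
#' @export
sliding_std <- function(latencies, window) {
  stopifnot(window >= 2)
  n <- length(latencies)
  if (window > n) {
    warning("window exceeds the trace length")
    return(numeric(0))
  }
  x <- latencies
  ok <- !is.na(x)
  x0 <- ifelse(ok, x, 0)
  cs <- cumsum(x0); cs2 <- cumsum(x0^2); ck <- cumsum(ok)
  idx <- window:n
  s <- cs[idx] - c(0, cs)[idx - window + 1L]
  s2 <- cs2[idx] - c(0, cs2)[idx - window + 1L]
  k <- ck[idx] - c(0, ck)[idx - window + 1L]
  out <- rep(NA_real_, length(idx))
  pos <- k > 0
  out[pos] <- sqrt(pmax(s2[pos] / k[pos] - (s[pos] / k[pos])^2, 0))
  out
}

#' Power-law fit of latency fluctuations near the intermittent phase
#'
#' As the stabilization latency approaches its saturated value `l_c`, the
#' latency fluctuations grow as a power law of the remaining distance.
#' Fits `ln(sigma)` against `ln((l_c - L_ST)/l_c)` by ordinary least
#' squares; the slope is the power-law exponent (negative when sigma
#' diverges toward `l_c`).  Points with `L_ST >= l_c` are excluded with a
#' warning; at least 3 valid points are required.
#'
#' @param sigmas Fluctuation standard deviations, ms.
#' @param l_st Stabilization latencies, ms.
#' @param l_c Saturated (intermittent-phase) latency, ms.
#' @return An object of class `powerlaw_fit`: list with `exponent`,
#'   `intercept`, `r_squared`, `n_used`.
#' @export
fit_sigma_powerlaw <- function(sigmas, l_st, l_c) {
  stopifnot(length(sigmas) == length(l_st), l_c > 0, all(sigmas > 0))
  valid <- l_st < l_c
  if (any(!valid))
    warning(sprintf("%d point(s) with L_ST >= l_c excluded", sum(!valid)))
  if (sum(valid) < 3) stop("fewer than 3 valid points")
  x <- log((l_c - l_st[valid]) / l_c)
  y <- log(sigmas[valid])
  fit <- lm(y ~ x)
  # noiseless synthetic curves are exactly collinear; the perfect-fit
  # warning from summary.lm is expected there
  r2 <- if (all(abs(y - mean(y)) < 1e-12)) 1 else
    suppressWarnings(summary(fit)$r.squared)
  structure(list(exponent = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = r2, n_used = sum(valid)),
            class = "powerlaw_fit")
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  cat(sprintf("Power-law fit: exponent %.4f, intercept %.4f (R^2 %.4f, %d points)\n",
              x$exponent, x$intercept, x$r_squared, x$n_used))
  invisible(x)
}

#' Transition latency from the inflection of a latency profile
#'
#' Locates the latency separating the concave (non-chaotic) and convex
#' (chaotic) regimes of a latency-stretching profile: the profile is
#' smoothed by a centred moving average, second differences are computed
#' (values within `tol` of zero are treated as zero), and the estimate is
#' the smoothed latency at the first transition from a run of at least
#' `min_run` negative second differences to a run of at least `min_run`
#' positive ones.  Profiles with no such sign change (strictly concave,
#' or linear within tolerance) yield `NA` with `found = FALSE`.
#'
#' @param profile Latency profile, ms (one value per stimulation).
#' @param smoothing_window Moving-average window (odd values recommended);
#'   must be much shorter than the profile.
#' @param min_run Minimum run length on each side of the sign change.
#' @param tol Second differences within `tol` (ms) count as zero.
#' @return A list with `l_t` (estimated latency, ms, or `NA`), `index`
#'   (stimulation index of the transition, or `NA`) and `found`.
#' @export
estimate_transition_latency <- function(profile, smoothing_window,
                                        min_run = 5, tol = 1e-6) {
  n <- length(profile)
  stopifnot(smoothing_window >= 1, n > 3 * smoothing_window)
  sm <- as.numeric(stats::filter(profile,
                                 rep(1 / smoothing_window, smoothing_window),
                                 sides = 2))
  keep <- which(!is.na(sm))
  smv <- sm[keep]
  d2 <- diff(smv, differences = 2)
  s <- sign(d2)
  s[abs(d2) < tol] <- 0
  r <- rle(s)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  # zero runs (curvature below tolerance) are neutral: a qualifying
  # negative run may be separated from the positive run by zeros only
  nq <- length(r$values)
  for (q in seq_len(nq)) {
    if (!(r$values[q] == -1 && r$lengths[q] >= min_run)) next
    w <- q + 1L
    while (w <= nq && r$values[w] == 0) w <- w + 1L
    if (w <= nq && r$values[w] == 1 && r$lengths[w] >= min_run) {
      at <- starts[w]  # first index of the positive run
      idx <- keep[min(at + 1L, length(keep))]
      return(list(l_t = sm[idx], index = idx, found = TRUE))
    }
  }
  list(l_t = NA_real_, index = NA_integer_, found = FALSE)
}
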