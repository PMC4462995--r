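# Synthetic test-input generators: Bernoulli failure sequences, responder-
# driven latency traces, and sampled voltage spikes with electrode noise.
# These stand in for extracellular recordings; all are synthetic.

#' Independent Bernoulli failure sequence
#'
#' i.i.d. outcomes with failure probability `p_fail`
#' (1 = evoked spike, 0 = failure).
#'
#' @param n Sequence length.
#' @param p_fail Failure probability.
#' @param seed Optional integer seed.
#' @return Integer vector of 0/1 outcomes.
#' @export
simulate_bernoulli_sequence <- function(n, p_fail, seed = NULL) {
  stopifnot(p_fail >= 0, p_fail <= 1, n >= 0)
  if (!is.null(seed)) set.seed(seed)
  rbinom(n, 1L, 1 - p_fail)
}

#' Responder-driven synthetic latency trace
#'
#' Drives a [synthetic_latency_responder()] with a stimulus train and
#' records the emitted latencies (`NA` marks response failures).
#'
#' @param train A [make_stimulus_train()] object or numeric lag vector, ms.
#' @param responder A [synthetic_latency_responder()]; a fresh default one
#'   when `NULL`.
#' @param seed Optional integer seed.
#' @return Data frame `stim_index`, `time_ms`, `latency_ms`.
#' @export
simulate_latency_trace <- function(train, responder = NULL, seed = NULL) {
  lags <- if (inherits(train, "stimulus_train")) train$lags else train
  if (!is.null(seed)) set.seed(seed)
  if (is.null(responder)) responder <- synthetic_latency_responder()
  lat <- vapply(lags, function(tau) respond(responder, tau), numeric(1))
  data.frame(stim_index = seq_along(lags), time_ms = cumsum(lags),
             latency_ms = lat)
}

#' Sampled voltage spike with electrode noise
#'
#' Generates a synthetic extracellular spike waveform sampled at a fixed
#' interval, with a linear descent of known slope through the detection
#' threshold, plus additive Gaussian electrode noise.  Because the
#' noiseless template is affine around the threshold, the true crossing
#' time is known in closed form, which makes the waveform an exact test
#' bed for [interpolate_crossing_time()] and
#' [propagate_threshold_noise()].
#'
#' @param n_samples Number of samples.
#' @param sample_interval_us Sampling interval, us (default 20).
#' @param baseline_uv Baseline voltage, uV.
#' @param trough_uv Spike trough voltage, uV.
#' @param descent_start Sample index where the descent begins.
#' @param slope_uv_per_sample Descent slope magnitude, uV per sample
#'   (default 15, a typical inter-sample voltage change in the crossing
#'   region).
#' @param threshold_uv Detection threshold, uV.
#' @param noise_sd_uv Additive Gaussian noise sd, uV (default 2.14, the
#'   typical amplified electrode noise level).
#' @param seed Optional integer seed.
#' @return A list with `time_ms`, `voltage_uv`, `threshold_uv`,
#'   `true_crossing_ms` (crossing of the noiseless template),
#'   `slope_uv_per_sample`, `sample_interval_us`.
#' @export
simulate_voltage_spike <- function(n_samples = 100, sample_interval_us = 20,
                                   baseline_uv = 0, trough_uv = -150,
                                   descent_start = 20,
                                   slope_uv_per_sample = 15,
                                   threshold_uv = -25, noise_sd_uv = 2.14,
                                   seed = NULL) {
  stopifnot(threshold_uv < baseline_uv, threshold_uv > trough_uv,
            slope_uv_per_sample > 0)
  if (!is.null(seed)) set.seed(seed)
  i <- seq_len(n_samples) - 1L
  descent_len <- ceiling((baseline_uv - trough_uv) / slope_uv_per_sample)
  v <- baseline_uv - pmax(0, pmin(i - descent_start, descent_len)) *
    slope_uv_per_sample
  v <- pmax(v, trough_uv)
  # recovery back to baseline after a short plateau
  rec <- descent_start + descent_len + 5
  v[i > rec] <- pmin(baseline_uv,
                     trough_uv + (i[i > rec] - rec) * slope_uv_per_sample / 3)
  true_cross <- (descent_start +
                 (baseline_uv - threshold_uv) / slope_uv_per_sample) *
    sample_interval_us / 1000
  if (noise_sd_uv > 0) v <- v + rnorm(n_samples, 0, noise_sd_uv)
  list(time_ms = i * sample_interval_us / 1000, voltage_uv = v,
       threshold_uv = threshold_uv, true_crossing_ms = true_cross,
       slope_uv_per_sample = slope_uv_per_sample,
       sample_interval_us = sample_interval_us)
}

#' Detect the first downward threshold crossing in a sampled trace
#'
#' Scans a sampled voltage trace for the first pair of consecutive samples
#' with `v1 >= threshold > v2` and returns the interpolated crossing time.
#'
#' @param spike A [simulate_voltage_spike()] object, or a list with
#'   `time_ms`, `voltage_uv`, `sample_interval_us`.
#' @param threshold_uv Detection threshold, uV (defaults to the trace's).
#' @return Crossing time in ms, or `NA` when no crossing is found.
#' @export
detect_crossing <- function(spike, threshold_uv = spike$threshold_uv) {
  v <- spike$voltage_uv
  i <- which(v[-length(v)] >= threshold_uv & v[-1] < threshold_uv)
  if (!length(i)) return(NA_real_)
  i <- i[1]
  interpolate_crossing_time(spike$time_ms[i], v[i], v[i + 1], threshold_uv,
                            spike$sample_interval_us)
}
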