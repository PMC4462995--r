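#' Build a stimulation train
#'
#' Generates the sequence of time-lags between consecutive stimulations for
#' the single-neuron protocols: strictly periodic, block-wise alternating
#' between two lags, i.i.d. uniform lags, or a custom lag sequence.
#' Stimulus times are the cumulative sums of the lags.
#'
#' @param mode One of `"periodic"`, `"alternating_block"`,
#'   `"uniform_random"`, `"custom"`.
#' @param count Number of stimulations.
#' @param tau Lag in ms (periodic mode).
#' @param lags The two alternating lags in ms (alternating_block mode).
#' @param block_length Number of repeats of each lag before switching
#'   (alternating_block mode).
#' @param range Lower and upper lag bound in ms (uniform_random mode).
#' @param custom_lags Lag sequence in ms (custom mode).
#' @param seed Optional integer seed (uniform_random mode).
#' @return An object of class `stimulus_train` with elements `lags`,
#'   `times` (cumulative, ms) and `mode`.
#' @examples
#' make_stimulus_train("alternating_block", count = 6, lags = c(20, 300),
#'                     block_length = 1)$lags
#' @export
make_stimulus_train <- function(mode = c("periodic", "alternating_block",
                                         "uniform_random", "custom"),
                                count, tau = NULL, lags = NULL,
                                block_length = 1, range = NULL,
                                custom_lags = NULL, seed = NULL) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  lag_seq <- switch(mode,
    periodic = {
      stopifnot(is.numeric(tau), length(tau) == 1L)
      rep(tau, count)
    },
    alternating_block = {
      stopifnot(is.numeric(lags), length(lags) == 2L, block_length >= 1)
      rep(rep(lags, each = block_length), length.out = count)
    },
    uniform_random = {
      stopifnot(is.numeric(range), length(range) == 2L)
      runif(count, range[1], range[2])
    },
    custom = {
      stopifnot(is.numeric(custom_lags))
      if (!missing(count) && length(custom_lags) != count)
        stop("'custom_lags' length must equal 'count'")
      custom_lags
    })
  if (any(lag_seq <= 0)) stop("all lags must be positive")
  structure(list(lags = lag_seq, times = cumsum(lag_seq), mode = mode),
            class = "stimulus_train")
}

#' @export
print.stimulus_train <- function(x, ...) {
  cat(sprintf("Stimulus train (%s): %d stimulations, mean lag %.2f ms (%.2f Hz)\n",
              x$mode, length(x$lags), mean(x$lags), 1000 / mean(x$lags)))
  invisible(x)
}

#' Periodic-limit failure fraction
#'
#' Expected response-failure fraction of a neuron with critical frequency
#' `f_c` under sustained periodic stimulation at `f_stim`:
#' `max(0, 1 - f_c / f_stim)`.  This is the stationary limit of the
#' forgetting-kernel law for strictly periodic drive.
#'
#' @param f_stim Stimulation frequency, Hz.
#' @param f_c Critical frequency, Hz.
#' @return A probability.
#' @examples
#' predict_failure_fraction(12, 5.5)  # ~0.54
#' predict_failure_fraction(7, 5.5)   # ~0.21
#' @export
predict_failure_fraction <- function(f_stim, f_c) {
  stopifnot(all(f_stim > 0), all(f_c > 0))
  pmax(0, 1 - f_c / f_stim)
}

#' Predicted mean ISI and firing rate under slow lag alternation
#'
#' For a train whose lag alternates slowly (each lag repeated long enough
#' for the failure probability to equilibrate within a block), lags below
#' the critical period saturate the effective inter-spike interval at
#' \eqn{\tau_C}, while longer lags pass through unchanged.  The predicted
#' mean ISI is the unweighted average over blocks of the per-block
#' effective ISI, and the rate is its reciprocal.
#'
#' @param train A [make_stimulus_train()] object (or numeric lag vector).
#' @param tau_c Critical period, ms.
#' @return A list with `mean_isi_ms` and `rate_hz`.
#' @examples
#' tr <- make_stimulus_train("alternating_block", count = 10,
#'                           lags = c(20, 300), block_length = 1)
#' predict_mean_isi_and_rate(tr, tau_c = 160)  # ISI 230 ms, rate ~4.3 Hz
#' @export
predict_mean_isi_and_rate <- function(train, tau_c) {
  lags <- if (inherits(train, "stimulus_train")) train$lags else train
  if (!length(lags)) stop("empty stimulus train")
  stopifnot(tau_c > 0)
  blocks <- rle(lags)$values
  eff <- ifelse(blocks < tau_c, tau_c, blocks)
  mean_isi <- mean(eff)
  list(mean_isi_ms = mean_isi, rate_hz = 1000 / mean_isi)
}

#' Critical per-stimulation failure probability for chain survival
#'
#' In a topology where activity propagates along chains of average length
#' `chain_length` that terminate in a branch into `branching` chains, spike
#' birth outweighs death as long as
#' `branching * (1 - p)^chain_length > 1`.  The supremum admissible
#' baseline failure probability is therefore
#' `1 - branching^(-1/chain_length)`.
#'
#' @param branching Branching factor at the chain end (>= 1).
#' @param chain_length Average chain length (>= 1).
#' @return The critical probability.
#' @examples
#' chain_critical_failure_probability(2, 9)  # ~0.0741, below 0.075
#' @export
chain_critical_failure_probability <- function(branching, chain_length) {
  stopifnot(branching >= 1, chain_length >= 1)
  1 - branching^(-1 / chain_length)
}

#' Ion-count timing floor of an evoked spike
#'
#' Order-of-magnitude estimate of the intrinsic timing precision of a
#' spike: the number of ions transported is `Q = C * dV / e` (membrane
#' capacitance times spike voltage excursion over the elementary charge),
#' and treating their emission as a simple stochastic process over the
#' spike duration gives an expected timing deviation of
#' `duration / sqrt(Q)`.
#'
#' @param capacitance Membrane capacitance, F (typical soma ~1e-11).
#' @param delta_v Voltage excursion during the spike, V (~0.1).
#' @param spike_duration_ms Spike duration, ms (~1).
#' @return A list with `ion_count` and `timing_sd_us`.
#' @examples
#' timing_noise_floor(1e-11, 0.1, 1)
#' @export
timing_noise_floor <- function(capacitance, delta_v, spike_duration_ms) {
  stopifnot(capacitance > 0, delta_v > 0, spike_duration_ms > 0)
  q <- capacitance * delta_v / 1.602176634e-19
  list(ion_count = q, timing_sd_us = spike_duration_ms * 1000 / sqrt(q))
}
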