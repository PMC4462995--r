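#' Predicted failure-probability profile for a cyclic lag sequence
#'
#' Evaluates the forgetting-kernel prediction of the per-stimulation
#' response-failure probability for a cyclically repeated lag sequence:
#' \deqn{P(i) = A \sum_{m=i-L}^{i-1} \frac{\tau_C - \tau_{(m)}}{\tau_C}
#'       e^{-\alpha (i-m)}, \qquad
#'       A = 1 / \sum_{j=1}^{L} e^{-\alpha j},}
#' with cyclic indexing of the lags (negative `m` wraps around) and the
#' result clamped to \[0, 1\].  The normalization makes `P(i) = 1` when all
#' lags are zero; for a constant lag the profile reduces exactly to the
#' periodic-limit value \eqn{(\tau_C - \tau)/\tau_C} for every
#' \eqn{\alpha > 0}.  The canonical design uses 80 stimulations per
#' recurrence; any length is accepted with `A` recomputed accordingly.
#'
#' @param lags Lag sequence, ms (one recurrence period).
#' @param tau_c Critical period, ms.
#' @param alpha Forgetting exponent (> 0).
#' @return Vector of failure probabilities, one per stimulation index.
#' @examples
#' p <- predicted_failure_profile(rep(c(1000/12, 1000/7), each = 40),
#'                                tau_c = 1000/5.5, alpha = 1.1)
#' round(range(p), 2)
#' @export
predicted_failure_profile <- function(lags, tau_c, alpha) {
  if (any(lags < 0)) stop("lags must be non-negative")
  stopifnot(tau_c > 0, alpha > 0)
  L <- length(lags)
  if (L < 1L) stop("empty lag sequence")
  w <- exp(-alpha * seq_len(L))
  a <- 1 / sum(w)
  term <- (tau_c - lags) / tau_c
  # P(i) = A * sum_d w[d] * term[(i - d) mod L], d = 1..L
  p <- numeric(L)
  for (d in seq_len(L)) {
    idx <- ((seq_len(L) - 1L - d) %% L) + 1L
    p <- p + w[d] * term[idx]
  }
  pmin(pmax(a * p, 0), 1)
}

#' Fit the forgetting exponent to an observed failure profile
#'
#' Least-squares fit of the forgetting exponent \eqn{\alpha} of
#' [predicted_failure_profile()] to an observed per-stimulation failure
#' probability profile, by a coarse grid search followed by golden-section
#' refinement inside the bracketing grid cell.  Ties on the grid resolve
#' to the smallest minimizer.  With constant lags the profile does not
#' depend on \eqn{\alpha} and the fit is flagged unidentifiable.
#'
#' @param observed Observed failure probabilities per stimulation index,
#'   in \[0, 1\].
#' @param lags Lag sequence, ms (same length as `observed`).
#' @param tau_c Critical period, ms.
#' @param alpha_grid Coarse grid of candidate exponents.
#' @return An object of class `alpha_fit`: list with `alpha`, `sse`,
#'   `identifiable`, `fitted` (profile at the optimum), `observed`.
#' @examples
#' lags <- rep(c(1000/12, 1000/7), each = 40)
#' obs <- predicted_failure_profile(lags, 1000/5.5, alpha = 1.1)
#' fit_forgetting_alpha(obs, lags, 1000/5.5)$alpha
#' @export
fit_forgetting_alpha <- function(observed, lags, tau_c,
                                 alpha_grid = seq(0.05, 5, by = 0.05)) {
  stopifnot(length(observed) == length(lags),
            all(observed >= 0), all(observed <= 1))
  if (length(unique(lags)) == 1L) {
    warning("constant lags: the forgetting exponent is unidentifiable")
    return(structure(list(alpha = NA_real_, sse = NA_real_,
                          identifiable = FALSE, fitted = NULL,
                          observed = observed),
                     class = "alpha_fit"))
  }
  sse <- function(a)
    sum((observed - predicted_failure_profile(lags, tau_c, a))^2)
  grid_sse <- vapply(alpha_grid, sse, numeric(1))
  i <- which.min(grid_sse)  # first minimum on ties
  lo <- alpha_grid[max(1L, i - 1L)]
  hi <- alpha_grid[min(length(alpha_grid), i + 1L)]
  opt <- optimize(sse, c(lo, hi))
  # keep the grid point if refinement did not improve (flat objective)
  if (opt$objective <= grid_sse[i]) {
    alpha <- opt$minimum
    obj <- opt$objective
  } else {
    alpha <- alpha_grid[i]
    obj <- grid_sse[i]
  }
  structure(list(alpha = alpha, sse = obj, identifiable = TRUE,
                 fitted = predicted_failure_profile(lags, tau_c, alpha),
                 observed = observed),
            class = "alpha_fit")
}

#' @export
print.alpha_fit <- function(x, ...) {
  if (!x$identifiable) {
    cat("Forgetting-exponent fit: unidentifiable (constant lags)\n")
  } else {
    cat(sprintf("Forgetting-exponent fit: alpha = %.3f (SSE %.4g, %d points)\n",
                x$alpha, x$sse, length(x$observed)))
  }
  invisible(x)
}

#' Empirical vs. Bernoulli pattern probabilities
#'
#' Tests the independence of response failures: slides a window of `k`
#' consecutive outcomes (stride 1) over a binary response sequence
#' (1 = evoked spike, 0 = failure), tabulates the empirical frequency of
#' each of the `2^k` patterns, and compares with the product-rule
#' expectation `p^(#failures) * (1-p)^(#spikes)` at the empirical failure
#' fraction `p`.  Binomial standard errors use the window count; with
#' overlapping windows they are approximate.
#'
#' @param seq Binary outcome vector (values 0/1).
#' @param k Window length.
#' @return A data frame of class `pattern_probs` with columns `pattern`
#'   (e.g. `"1011"`, temporal order), `empirical`, `expected`, `se`, and
#'   attributes `p_fail`, `n_windows`.
#' @examples
#' s <- simulate_bernoulli_sequence(1e4, p_fail = 0.4, seed = 1)
#' head(pattern_probabilities(s, 4))
#' @export
pattern_probabilities <- function(seq, k) {
  if (!all(seq %in% c(0, 1))) stop("'seq' must be binary (0 = failure)")
  n <- length(seq)
  if (k > n) stop("'k' exceeds the sequence length")
  nw <- n - k + 1L
  # windows in temporal order: embed() returns reversed columns
  m <- stats::embed(seq, k)[, k:1, drop = FALSE]
  id <- as.vector(m %*% 2^((k - 1):0))
  emp <- tabulate(id + 1L, 2^k) / nw
  p <- mean(seq == 0)
  bits <- t(vapply(0:(2^k - 1),
                   function(v) as.integer(intToBits(v))[k:1],
                   integer(k)))
  ones <- rowSums(bits)
  expected <- p^(k - ones) * (1 - p)^ones
  out <- data.frame(
    pattern = apply(bits, 1, paste, collapse = ""),
    empirical = emp, expected = expected,
    se = sqrt(expected * (1 - expected) / nw))
  structure(out, class = c("pattern_probs", "data.frame"),
            p_fail = p, n_windows = nw)
}

#' Run-length distributions of failures and spikes
#'
#' For a binary response sequence, `P0(m)` is the empirical probability
#' that a spike is followed by exactly `m` consecutive failures before the
#' next spike (`m >= 0`), and `P1(m)` the analogous spike run length
#' bounded by failures.  Runs truncated at the sequence boundaries are
#' dropped (unbiased for interior runs).  Under independent failures at
#' rate `p` the laws are geometric: `P0(m) = (1-p) p^m` and
#' `P1(m) = p (1-p)^m`; the returned theory curves use the empirical `p`.
#'
#' @param seq Binary outcome vector (1 = evoked spike, 0 = failure).
#' @return An object of class `run_length_dist`: list with `p_fail`, and
#'   data frames `p0`, `p1` (`m`, `prob`, `theory`), each empty and
#'   flagged via the `missing_symbol` element when the sequence lacks the
#'   bounding symbol.
#' @export
run_length_distributions <- function(seq) {
  if (!all(seq %in% c(0, 1))) stop("'seq' must be binary (0 = failure)")
  p <- mean(seq == 0)
  gap_dist <- function(anchor) {
    idx <- which(seq == anchor)
    if (length(idx) < 2L)
      return(data.frame(m = integer(0), prob = numeric(0),
                        theory = numeric(0)))
    gaps <- diff(idx) - 1L
    m <- 0:max(gaps)
    prob <- tabulate(gaps + 1L, max(gaps) + 1L) / length(gaps)
    th <- if (anchor == 1L) (1 - p) * p^m else p * (1 - p)^m
    data.frame(m = m, prob = prob, theory = th)
  }
  p0 <- gap_dist(1L)
  p1 <- gap_dist(0L)
  structure(list(p_fail = p, p0 = p0, p1 = p1,
                 missing_symbol = c(p0 = nrow(p0) == 0, p1 = nrow(p1) == 0)),
            class = "run_length_dist")
}

#' @export
print.run_length_dist <- function(x, ...) {
  cat(sprintf("Run-length distributions: failure fraction %.3f\n", x$p_fail))
  cat(sprintf("  P0 (failure runs): %d lengths; P1 (spike runs): %d lengths\n",
              nrow(x$p0), nrow(x$p1)))
  if (any(x$missing_symbol))
    cat("  note: a bounding symbol is absent; the affected distribution is empty\n")
  invisible(x)
}

#' @export
plot.run_length_dist <- function(x, which = c("p0", "p1"), ...) {
  which <- match.arg(which)
  d <- x[[which]]
  d <- d[d$prob > 0, ]
  plot(d$m, log(d$prob), xlab = "run length m", ylab = "ln probability", ...)
  lines(d$m, log(d$theory), lty = 2)
  legend("topright", c("empirical", "geometric theory"),
         pch = c(1, NA), lty = c(NA, 2), bty = "n")
  invisible(x)
}

#' Empirical failure fraction and conserved mean ISI
#'
#' Under periodic drive with lag `tau`, the failure fraction `P_fail`
#' determines the mean inter-spike interval as `tau / (1 - P_fail)`; in
#' the intermittent phase this saturates at the critical period.  Returns
#' both from a binary outcome sequence.  With no spikes at all the ISI is
#' undefined and returned as `NA` with a warning.
#'
#' @param seq Binary outcome vector (1 = evoked spike, 0 = failure).
#' @param tau Stimulation lag, ms.
#' @return A list with `p_fail` and `mean_isi_ms`.
#' @export
empirical_failure_fraction_and_isi <- function(seq, tau) {
  if (!all(seq %in% c(0, 1))) stop("'seq' must be binary (0 = failure)")
  stopifnot(tau > 0)
  p <- mean(seq == 0)
  if (p == 1) {
    warning("all stimulations failed: mean ISI undefined")
    return(list(p_fail = p, mean_isi_ms = NA_real_))
  }
  list(p_fail = p, mean_isi_ms = tau / (1 - p))
}
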