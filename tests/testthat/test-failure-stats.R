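# Failure-sequence statistics, the forgetting-exponent fit, and the
# sampled-trace analysis operations.

test_that("the predicted failure profile obeys its normalization and limits", {
  # all lags zero: normalization sets every probability to 1
  expect_equal(predicted_failure_profile(rep(0, 80), 150, 1.1), rep(1, 80))
  # all lags at tau_c: every term vanishes
  expect_equal(predicted_failure_profile(rep(150, 80), 150, 1.1), rep(0, 80))
  # constant lags reduce to the periodic-limit value for any alpha
  for (alpha in c(0.3, 1.1, 1.4, 2.5)) {
    p <- predicted_failure_profile(rep(50, 80), 150, alpha)
    expect_equal(p, rep((150 - 50) / 150, 80), tolerance = 1e-12)
  }
})

test_that("the block profile plateaus at the periodic-limit values", {
  # 40 stimulations at 12 Hz then 40 at 7 Hz, tau_c = 1/5.5 s, alpha 1.1:
  # plateaus near 0.54 and 0.21 away from the block boundaries
  lags <- rep(c(1000 / 12, 1000 / 7), each = 40)
  p <- predicted_failure_profile(lags, 1000 / 5.5, alpha = 1.1)
  expect_equal(mean(p[20:40]), 1 - 5.5 / 12, tolerance = 0.01)
  expect_equal(mean(p[60:80]), 1 - 5.5 / 7, tolerance = 0.01)

  # direct-summation oracle at a handful of indices
  direct <- function(i, lags, tau_c, alpha) {
    L <- length(lags)
    a <- 1 / sum(exp(-alpha * seq_len(L)))
    m <- (i - L):(i - 1)
    tau_m <- lags[(m %% L) + 1]
    min(max(a * sum((tau_c - tau_m) / tau_c * exp(-alpha * (i - m))), 0), 1)
  }
  for (i in c(1, 7, 40, 41, 63, 80))
    expect_equal(p[i], direct(i - 1, lags, 1000 / 5.5, 1.1),
                 tolerance = 1e-12)
})

test_that("the forgetting exponent is recovered from profiles", {
  lags <- rep(c(1000 / 12, 1000 / 7), each = 40)
  tc <- 1000 / 5.5
  truth <- predicted_failure_profile(lags, tc, alpha = 1.1)
  # noiseless recovery
  fit <- fit_forgetting_alpha(truth, lags, tc)
  expect_true(fit$identifiable)
  expect_lt(abs(fit$alpha - 1.1), 0.05)
  # binomial noise at 200 recurrences per index: Monte-Carlo recovery
  # (individual replicates scatter with sd ~0.1; the mean absolute error
  # over replicates stays inside the band)
  set.seed(6)
  errs <- replicate(20, {
    obs <- rbinom(80, 200, truth) / 200
    abs(fit_forgetting_alpha(obs, lags, tc)$alpha - 1.1)
  })
  expect_lt(mean(errs), 0.2)
  # constant lags: alpha cancels, flagged unidentifiable
  expect_warning(flat <- fit_forgetting_alpha(rep(0.3, 80), rep(60, 80), tc),
                 "unidentifiable")
  expect_false(flat$identifiable)
  expect_true(is.na(flat$alpha))
})

test_that("pattern probabilities match the independence product rule", {
  # degenerate all-spike sequence
  pp1 <- pattern_probabilities(rep(1L, 50), 4)
  expect_equal(pp1$empirical[pp1$pattern == "1111"], 1)
  expect_equal(sum(pp1$empirical), 1)

  # i.i.d. failures at 0.4: P(1111) = 0.6^4, all patterns within 3 SE
  s <- simulate_bernoulli_sequence(1e5, 0.4, seed = 1)
  pp <- pattern_probabilities(s, 4)
  expect_equal(pp$expected[pp$pattern == "1111"], 0.6^4, tolerance = 0.01)
  expect_true(all(abs(pp$empirical - pp$expected) <= 3 * pp$se))
  expect_error(pattern_probabilities(s[1:3], 4), "length")
})

test_that("failure sequences from a driven impedance neuron look Bernoulli", {
  # intermittent phase: 12 Hz drive on an f_C = 9 Hz neuron
  d <- drive_neuron(neuron_spec(tau_c = 1000 / 9),
                    times = seq(1000 / 12, 1e4 * 1000 / 12, by = 1000 / 12),
                    seed = 5)
  pp <- pattern_probabilities(d$outcomes, 4)
  expect_true(all(abs(pp$empirical - pp$expected) <= 3 * pp$se))
  rl <- run_length_distributions(d$outcomes)
  d0 <- rl$p0[rl$p0$prob > 0 & rl$p0$m <= 6, ]
  fit <- lm(log(prob) ~ m, d0)
  expect_gt(summary(fit)$r.squared, 0.97)
  expect_equal(unname(coef(fit)[2]), log(rl$p_fail), tolerance = 0.12)
})

test_that("run-length laws are geometric with the empirical rate", {
  s <- simulate_bernoulli_sequence(1e5, 0.4, seed = 7)
  rl <- run_length_distributions(s)
  d0 <- rl$p0[rl$p0$prob > 0 & rl$p0$m <= 8, ]
  fit <- lm(log(prob) ~ m, d0)
  expect_gt(summary(fit)$r.squared, 0.99)
  expect_equal(unname(coef(fit)[2]), log(0.4), tolerance = 0.05)
  expect_equal(unname(coef(fit)[1]), log(0.6), tolerance = 0.05)
  # spike runs: slope ln(1-p), intercept ln(p)
  d1 <- rl$p1[rl$p1$prob > 0 & rl$p1$m <= 8, ]
  fit1 <- lm(log(prob) ~ m, d1)
  expect_equal(unname(coef(fit1)[2]), log(0.6), tolerance = 0.05)

  # a sequence with no failures leaves the failure-run law empty, flagged
  rl0 <- run_length_distributions(rep(1L, 100))
  expect_equal(nrow(rl0$p1), 0L)
  expect_true(rl0$missing_symbol[["p1"]])
})

test_that("failure fraction determines the conserved mean ISI", {
  expect_equal(empirical_failure_fraction_and_isi(rep(1L, 10), 100)$mean_isi_ms,
               100)
  s <- c(rep(0L, 5), rep(1L, 5))
  expect_equal(empirical_failure_fraction_and_isi(s, 75)$mean_isi_ms, 150)
  set.seed(8)
  s2 <- simulate_bernoulli_sequence(1e4, 0.25)
  isi <- empirical_failure_fraction_and_isi(s2, 100)$mean_isi_ms
  expect_equal(isi, 100 / 0.75, tolerance = 0.03)
  expect_warning(out <- empirical_failure_fraction_and_isi(rep(0L, 10), 100),
                 "undefined")
  expect_true(is.na(out$mean_isi_ms))
})

test_that("crossing interpolation is exact on affine segments", {
  expect_equal(interpolate_crossing_time(0, -25, -30, -25), 0)
  expect_equal(interpolate_crossing_time(0, -20, -30, -25), 0.010)
  expect_equal(interpolate_crossing_time(0, -10, -30, -25), 0.015)
  expect_error(interpolate_crossing_time(0, -25, -25, -25), "degenerate")
  expect_error(interpolate_crossing_time(0, -10, -20, -25), "bracket")

  # reconstructing crossings of a sampled ramp recovers the analytic value
  slope <- -13.7  # uV per sample
  v0 <- 100
  for (th in c(37.2, 12.9, -55.5)) {
    i <- floor((th - v0) / slope)
    tt <- interpolate_crossing_time(i * 0.02, v0 + slope * i,
                                    v0 + slope * (i + 1), th)
    analytic <- (th - v0) / slope * 0.02
    expect_equal(tt, analytic, tolerance = 1e-12)
  }
})

test_that("electrode noise propagates linearly into timing uncertainty", {
  expect_equal(round(propagate_threshold_noise(2.14, 15, 20), 2), 2.85)
  expect_identical(propagate_threshold_noise(0, 15), 0)
  expect_equal(propagate_threshold_noise(2.14, 30),
               propagate_threshold_noise(2.14, 15) / 2)
  expect_error(propagate_threshold_noise(2.14, 0), "positive")
})

test_that("the rolling standard deviation uses the population convention", {
  expect_equal(sliding_std(rep(5, 100), 10), rep(0, 91))
  # alternating L +/- a has population sd exactly a over even windows
  x <- 5 + rep(c(0.3, -0.3), 50)
  expect_equal(sliding_std(x, 10), rep(0.3, 91), tolerance = 1e-12)
  # Gaussian jitter of 14 us recovered within 3 SE of the estimator
  set.seed(9)
  lat <- rnorm(4000, 5, 0.014)
  s <- sliding_std(lat, 1000)
  expect_lt(abs(mean(s) - 0.014), 3 * 0.014 / sqrt(2 * 999))
  # failures are excluded within the window
  lat[seq(1, 4000, by = 7)] <- NA
  expect_true(all(is.finite(sliding_std(lat, 1000))))
  expect_warning(out <- sliding_std(1:5, 10), "window")
  expect_length(out, 0)
})

test_that("the power-law exponent is recovered exactly on noiseless curves", {
  lc <- 11.28
  lst <- seq(4, 11, length.out = 9)
  for (gamma in c(-0.8, -1.6)) {
    sig <- 0.004 * ((lc - lst) / lc)^gamma
    fit <- fit_sigma_powerlaw(sig, lst, lc)
    expect_lt(abs(fit$exponent - gamma), 1e-10)
    expect_gt(fit$r_squared, 1 - 1e-10)
  }
  # constant sigma: slope zero
  flat <- fit_sigma_powerlaw(rep(0.005, 5), lst[1:5], lc)
  expect_lt(abs(flat$exponent), 1e-12)
  # points at or beyond l_c are excluded with a warning
  expect_warning(f2 <- fit_sigma_powerlaw(c(0.01, 0.02, 0.03, 0.04),
                                          c(4, 6, 8, 12), lc), "excluded")
  expect_equal(f2$n_used, 3L)
  expect_error(fit_sigma_powerlaw(c(1, 2), c(4, 6), lc), "3 valid")
})

test_that("the concave-to-convex transition latency is located", {
  i <- 1:2000
  prof <- 6 * (1 - exp(-i / 300)) + 1.0 * exp((i - 2000) / 150)
  # analytic inflection of the generating function
  g <- function(x) 6 / 300^2 * exp(-x / 300) - 1 / 150^2 * exp((x - 2000) / 150)
  true_i <- uniroot(g, c(1, 2000))$root
  est <- estimate_transition_latency(prof, smoothing_window = 51, tol = 0)
  expect_true(est$found)
  expect_lt(abs(est$index - true_i), 51)
  expect_equal(est$l_t, prof[round(true_i)], tolerance = 0.02)
  # strictly concave and linear profiles have no transition
  expect_false(estimate_transition_latency(6 * (1 - exp(-i / 300)), 51)$found)
  expect_false(estimate_transition_latency(0.001 * i, 51)$found)
})
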