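# Network engine: event semantics, delayed delivery, rate summaries, and
# the cooperative suppression of firing rates.

make_loop <- function(delays = c(6, 9.5), fc = 1000) {
  # two mutually connected neurons with huge f_C (no failures)
  topo <- build_topology(2, p_extra = 0, fc_mode = "custom",
                         fc_custom = rep(fc, 2), seed = 1)
  topo$edges$delay_ms <- delays[order(topo$edges$pre)]
  topo
}

kick <- function(neuron = 1, t = 0, strength = 2) {
  impednet:::as_schedule(data.frame(neuron = neuron, time_ms = t,
                                    strength = strength))
}

test_that("rest is a fixed point: no stimulation, no events", {
  topo <- build_topology(20, seed = 1)
  log <- simulate_network(topo, list(), duration_ms = 1000, seed = 1)
  expect_equal(nrow(log), 0L)
})

test_that("a two-neuron mutual loop alternates with period 15.5 ms", {
  # hand event-trace oracle: every +2 arrival exceeds threshold from any
  # post-reset voltage, so spikes circulate at delay_12 + delay_21
  log <- simulate_network(make_loop(), kick(), duration_ms = 500, seed = 1)
  sp <- log[log$kind == "spike", ]
  isi <- unlist(tapply(sp$time_ms, sp$neuron, diff))
  expect_true(all(abs(isi - 15.5) < 1e-9))
  # causality: neuron 2's first spike is exactly one delay after neuron 1's
  t1 <- min(sp$time_ms[sp$neuron == 1])
  t2 <- min(sp$time_ms[sp$neuron == 2])
  d12 <- make_loop()$edges$delay_ms[make_loop()$edges$pre == 1]
  expect_equal(t2 - t1, d12)
})

test_that("every spike and failure coincides with a crossing record", {
  topo <- build_topology(100, seed = 3)
  log <- simulate_network(topo, initial_stimulation_schedule(100),
                          duration_ms = 5000, seed = 3)
  cr <- paste(log$time_ms, log$neuron)[log$kind == "crossing"]
  out <- paste(log$time_ms, log$neuron)[log$kind %in% c("spike", "failure")]
  expect_true(all(out %in% cr))
  expect_equal(length(out), length(cr))
  expect_false(is.unsorted(log$time_ms))
})

test_that("identical seed and configuration give identical event logs", {
  topo <- build_topology(50, seed = 9)
  sched <- initial_stimulation_schedule(50, seed = 9)
  l1 <- simulate_network(topo, sched, duration_ms = 3000, seed = 4)
  l2 <- simulate_network(topo, sched, duration_ms = 3000, seed = 4)
  expect_identical(l1, l2)
  f1 <- tempfile(); f2 <- tempfile()
  write_event_log(l1, f1); write_event_log(l2, f2)
  expect_identical(readLines(f1), readLines(f2))
  unlink(c(f1, f2))
})

test_that("refractory neurons discard inputs", {
  # drive neuron 1 twice within its 2 ms refractory period: the second
  # stimulus is recorded but produces no crossing
  topo <- make_loop(fc = 1000)
  topo$edges <- topo$edges[0, ]  # isolate the neurons
  sched <- kick(neuron = c(1, 1), t = c(10, 11))
  log <- simulate_network(topo, sched, duration_ms = 100, seed = 1)
  expect_equal(sum(log$kind == "stimulus"), 2L)
  expect_equal(sum(log$kind == "crossing"), 1L)
})

test_that("firing-rate histogram counts, bins and mean obey the contract", {
  # a neuron spiking exactly every 100 ms sits in the [10, 10.5) Hz bin
  log <- structure(data.frame(time_ms = seq(4000, 58900, by = 100),
                              neuron = 1L,
                              kind = factor("spike",
                                levels = c("stimulus", "crossing",
                                           "spike", "failure"))),
                   class = c("event_log", "data.frame"),
                   n_neurons = 3L, duration_ms = 60000, dt = 0.05)
  h <- firing_rate_histogram(log, n = 3)
  expect_equal(h$rates[1], 10)
  expect_equal(sum(h$counts), 3)  # counts sum to n (two silent neurons)
  expect_equal(h$counts[h$bin_low_hz == 10], 1)
  expect_equal(h$mean_rate, sum(h$rates) / 3)

  empty <- log[0, ]
  attr(empty, "n_neurons") <- 3L; attr(empty, "duration_ms") <- 60000
  h0 <- firing_rate_histogram(empty, n = 3)
  expect_equal(h0$mean_rate, 0)
  expect_error(firing_rate_histogram(log, n = 3, window = c(4000, 70000)),
               "window")
})

test_that("network rates are suppressed toward the lowest critical frequency", {
  # cooperation property at reduced scale: mean rate below 1.05 x the
  # lowest mean f_C for both f_C configurations, across 3 seeds
  for (mode in c("two_point", "uniform")) {
    rate <- seed_mean_rate(1:3, n = 200, fc_mode = mode,
                           duration_ms = 20000)
    expect_gt(rate, 1)  # self-sustaining
    expect_lt(rate, 1.05 * 6.66)
  }
})

test_that("the mean rate is insensitive to the initialization scheme", {
  topo <- build_topology(1000, seed = 21)
  poisson_start <- simulate_network(topo, initial_stimulation_schedule(1000),
                                    duration_ms = 60000, seed = 21)
  single_start <- simulate_network(topo, kick(neuron = 1, t = 0),
                                   duration_ms = 60000, seed = 22)
  r1 <- firing_rate_histogram(poisson_start, 1000)$mean_rate
  r2 <- firing_rate_histogram(single_start, 1000)$mean_rate
  expect_equal(r1, r2, tolerance = 0.05)
})

test_that("sub-step delays trigger the rounding warning", {
  topo <- make_loop()
  topo$edges$delay_ms <- c(0.01, 9.5)
  expect_warning(simulate_network(topo, kick(), duration_ms = 10, seed = 1),
                 "rounded")
  expect_error(simulate_network(make_loop(), kick(), duration_ms = -5),
               "duration")
})
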