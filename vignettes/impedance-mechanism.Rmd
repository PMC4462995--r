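---
title: "The neuronal response impedance mechanism: model, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The neuronal response impedance mechanism: model, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(impednet)
```

## The model

`impednet` simulates excitatory networks of leaky integrate-and-fire (LIF)
neurons whose defining feature is *stochastic response failure*: a neuron
that crosses its firing threshold converts the crossing into an evoked
spike only with probability $1 - P_{fail}$, where $P_{fail}$ depends on how
hard the neuron has recently been driven.

In rescaled units (threshold 1, rest 0; one dimensionless weight unit is
16 mV of membrane potential) the voltage of neuron $i$ obeys

$$\frac{dV_i}{dt} = -\frac{V_i}{\tau} +
  \sum_j J_{ji} \sum_{t'} \delta(t - t' - D_{ji}) +
  J \sum_{t'} \delta(t - t'),$$

with membrane constant $\tau = 20$ ms, synaptic weights $J_{ji}$, delays
$D_{ji}$ drawn uniformly from 6–9.5 ms, and external stimulation of
strength $J$.  Inputs are pure impulses: the voltage jumps by the weight
and otherwise decays exponentially.  An above-threshold weight of 2 makes
every delivered impulse a threshold crossing on its own.

Each neuron carries a critical period $\tau_C$ (critical frequency
$f_C = 1/\tau_C$) and a forgetting exponent $\alpha$.  Writing $t(i,n)$
for the time of the $n$-th threshold crossing of neuron $i$, the failure
probability at that crossing is the kernel-weighted mean of how far the
completed inter-crossing intervals fell short of $\tau_C$:

$$P_{fail}(i,n) = \frac{\sum_{k<n}
  \bigl(1 - \tfrac{t(i,k+1) - t(i,k)}{\tau_C}\bigr) e^{-\alpha(n-k+1)}}
  {\sum_{k<n} e^{-\alpha(n-k+1)}},$$

clamped to $[0, 1]$ *after* the sum (clamping per term would destroy the
exact periodic reduction below).  The sum runs over all completed
intervals, **including the one ending at the current crossing**, which
carries the largest weight $e^{-2\alpha}$.  This detail matters
dynamically: the first crossing after a long silent interval is judged
mostly by that long interval (relative weight $1 - e^{-\alpha} \approx
0.75$ at $\alpha = 1.4$), so a recovering neuron becomes responsive
immediately.  We found that deferring the newest interval to the *next*
evaluation extinguishes all self-sustained network activity within about
a second of the end of external stimulation — the package therefore
evaluates the kernel inclusive of the newest interval, and only the very
first crossing of a neuron is unconditionally a spike.

Two consequences shape everything else:

* **Periodic limit.**  For strictly periodic drive at $f_{stim} > f_C$
  the kernel weights cancel and $P_{fail} = 1 - f_C/f_{stim}$ exactly,
  for every $\alpha > 0$ (`predict_failure_fraction()`).
* **Low-pass saturation.**  The conserved quantity is the mean
  inter-spike interval, $\tau/(1 - P_{fail}) \to \tau_C$: the neuron
  passes slow drive unchanged and attenuates fast drive to its critical
  frequency.

On a network in which activity circulates along chains, any neuron with a
low $f_C$ throttles every neuron downstream of it, so the population
firing rate is suppressed toward (and, with aperiodic inter-stimulus
lags, below) the lowest critical frequency present — cooperation through
a nodal property rather than through inhibitory links.

After an evoked spike the voltage is reset to $-0.5$, taking effect at
the end of a 2 ms absolute refractory period during which the neuron is
frozen and discards arriving inputs.  A response failure instead sets the
voltage to $0.2$ with no refractory period.

## Parameters and defaults

| parameter | default | units | meaning |
|---|---|---|---|
| `tau_m` | 20 | ms | membrane time constant |
| `v_threshold`, `v_stable` | 1, 0 | — | rescaled threshold and rest |
| `v_reset`, `v_fail` | −0.5, 0.2 | — | post-spike / post-failure voltage |
| `t_refractory` | 2 | ms | absolute refractory period after a spike |
| `tau_c` | 150 | ms | critical period ($f_C \approx 6.7$ Hz) |
| `alpha` | 1.4 | — | forgetting exponent of the failure kernel |
| `j` | 2 | — | above-threshold connection strength (32 mV) |
| `p_extra` | 0.1/N | — | supplemental-connection probability per ordered pair |
| delays | U(6, 9.5) | ms | synaptic delays |
| `dt` | 0.05 | ms | integration step |

The prototypical topology assigns every neuron exactly one pre- and one
post-synaptic partner (a uniform derangement) plus supplemental
above-threshold edges at `0.1/N` per ordered pair, giving each neuron a
second target with probability ≈ 0.1 and hence functional chains of
average length ≈ 9.  Critical frequencies are assigned either as a
two-point mixture of 6.66 and 14.28 Hz (critical periods exactly 150 and
70 ms) or uniformly between those frequencies.  Networks are started by a
50 Hz Poisson candidate process per neuron thinned by survival
$e^{-T/200\,\mathrm{ms}}$ and truncated at 1 s, after which activity is
self-sustaining; per-neuron rates are measured over 4–59 s in 0.5 Hz
bins.

## Numerics

**Event-driven leak.**  The engine (`simulate_network()`, implemented in
C++) follows forward-Euler semantics at `dt` = 0.05 ms: within a step,
all impulses due are accumulated, the leak factor $(1 - dt/\tau)$ is
applied once, and the threshold is tested once, so simultaneous arrivals
sum before a single crossing test.  Because the voltage changes only at
impulse arrivals, the engine applies the accumulated leak lazily in
closed form, $(1 - dt/\tau)^k$ over the $k$ silent steps — algebraically
identical to eager stepping, but the cost scales with the number of
events rather than with $N \times$ steps.  A full N = 2000, 60 s run
completes in well under a second, so both the test suite and the
acceptance script run every network configuration at full scale (three
seeds per configuration); reduced sizes (N = 200–1000) are used only in
unit tests of properties that do not depend on scale.

**Discreteness.**  Delays are rounded to the nearest integer number of
steps (with `dt` = 0.05 ms the rounding error is ≪ the 6–9.5 ms delay
spread; sub-step delays are clamped to one step with a warning), and
crossing times are recorded at step times without sub-step interpolation
— interpolation belongs to the analysis side
(`interpolate_crossing_time()`), mirroring how recorded spikes are
treated.  Inputs landing on the exact end-of-refractory step are
accepted; earlier ones are discarded outright, not buffered.

**Reproducibility.**  All randomness flows through R's RNG.  The engine
draws exactly one uniform variate per threshold crossing, in ascending
neuron-index order within a step, so a configuration plus a seed fixes
the event log byte-for-byte.  The spontaneous-stimulation generator draws
a per-neuron binomial count of steps and then samples distinct steps,
which is distributionally identical to (and vastly cheaper than) a
Bernoulli draw per neuron and step.

**Incremental kernel.**  The failure kernel is maintained by a
decay-and-add recursion (multiply numerator and denominator by
$e^{-\alpha}$, add the newest term with weight $e^{-2\alpha}$); the test
suite verifies agreement with brute-force summation over random crossing
histories to $10^{-12}$.

## Analysis procedures

`predicted_failure_profile()` evaluates the kernel prediction for a
cyclically repeated lag sequence with normalization $A = 1/\sum_{j=1}^{L}
e^{-\alpha j}$, so an all-zero lag sequence gives probability 1
everywhere; the canonical recurrence length is 80 but any length is
accepted with $A$ recomputed.  `fit_forgetting_alpha()` minimizes the
squared distance to an observed profile by a coarse grid (step 0.05) and
golden-section refinement in the bracketing cell, taking the smallest
minimizer on ties; constant-lag profiles are flagged unidentifiable
because $\alpha$ cancels there.

The stochasticity tests treat a binary outcome sequence against an
independence null at its empirical failure fraction:
`pattern_probabilities()` uses overlapping windows of stride 1 (the
stride is a design choice; overlap maximizes data use and the quoted
binomial standard errors are then approximate), and
`run_length_distributions()` anchors runs on the bounding symbol — for
each spike, the count of consecutive failures before the next spike —
dropping boundary-truncated runs, which makes the geometric laws
$P_0(m) = (1-p)p^m$ and $P_1(m) = p(1-p)^m$ exact for i.i.d. input.

`sliding_std()` uses the population convention (divide by the window
count) with failures excluded per window; at the customary window of
1000 the difference from the sample convention is far below reported
precision.  `estimate_transition_latency()` smooths with a centred
moving average, treats second differences within `tol` (default
$10^{-6}$ ms) as zero, and reports the first transition from a run of at
least 5 negative second differences to a run of at least 5 positive ones,
with zero runs neutral between them; gently curved profiles may need a
smaller `tol`, and strictly concave or linear profiles return
`found = FALSE`.

## The slow-alternation predictor

`predict_mean_isi_and_rate()` implements the block-averaged prediction
for slowly alternating lags: lags below $\tau_C$ contribute an effective
inter-spike interval of $\tau_C$, longer lags pass through, and the mean
is taken *unweighted over blocks* (for lags 20/300 ms and $\tau_C =
160$ ms: ISI $= 0.5(160+300) = 230$ ms, rate 4.3 Hz).  This is a
deliberate simplification — a 5–10 stimulation block at a short lag spans
only about one critical period — and simulated drives run some 10% below
it while remaining well under $f_C$; the property test asserts agreement
at 15%.

## The closed-loop controller and its responder

`adaptive_latency_controller()` implements the three-branch rule: after
each stimulation the next lag shrinks by $\Delta$ if the observed latency
is below the target $L_{ST}$, grows by $\Delta$ if above, and stays put
on exact equality.  Design choices: a response failure (no latency
observed) lengthens the lag, since failures arise from over-driving; lags
are clamped below at a configurable floor with a one-time warning;
history-dependent step sizes are out of scope.

Closed-loop experiments need something to close the loop against, so the
package ships a *phenomenological* latency responder
(`synthetic_latency_responder()`) — an explicit artifact, not a
biophysical model.  It combines (i) a monotone stationary latency map
$L^*(\tau) = L_0 + (L_C - L_0) e^{-(\tau - \tau_C)/s}$ for
$\tau \ge \tau_C$, saturating at $L_C$ in the intermittent regime;
(ii) slow exponential relaxation of an internal latency state toward
$L^*$ at $2\times10^{-4}$ per stimulation; (iii) a small fast component
(weight 0.05) of the instantaneous $L^*(\tau)$ in the emitted latency,
standing in for the ultra-fast sensitivity of real latencies to the
current lag — without it the slow state cannot inform the comparator and
the closed loop would random-walk; (iv) Gaussian jitter of 14 µs; and
(v) failures at the periodic-limit rate when driven above $f_C$.  With
the default calibration ($L_0 = 1$ ms, $L_C = 11$ ms, $\tau_C = 150$ ms,
$s = 52.6$ ms) the lag whose stationary latency is 5 ms equals 198.2 ms,
and the controller's smoothed lag settles within a few ms of that fixed
point.  No quantitative stationary map is available to calibrate against
beyond the relaxation-rate anchor, so every constant is a constructor
argument.

## What the synthetic generators do and do not emulate

The fixture generators produce i.i.d. Bernoulli failure sequences,
responder-driven latency traces, and sampled spike waveforms with a
linear descent of known slope (default 15 µV/sample at 20 µs sampling)
plus Gaussian electrode noise (default 2.14 µV).  They emulate the
*statistical structure* the analysis operations assume — independence,
exponential relaxation, affine threshold crossings — not the waveform
shapes, drifts, bursts or artifacts of real extracellular recordings.
Passing tests therefore certify the procedures' correctness on their
stated models, not their robustness to recording pathologies.  One
quantitative subtlety: interpolating between *two* independently noisy
samples pools the noise with weights $(1-f, f)$, so the Monte-Carlo
crossing-time spread is $\sqrt{2/3} \approx 0.82$ of the one-sample
propagation value $\sigma \cdot \mathrm{interval}/\Delta V$ returned by
`propagate_threshold_noise()`; the tests assert both the scaled value
and the bound.

## Known limitations

* The near-critical baseline-failure configuration (`extra_failure`
  preset, $C = 0.07$ against the chain-survival bound $p < 0.075$) is
  marginal by construction: at finite size, runs may lose self-sustained
  activity, and mean rates there vary strongly across seeds.
* No inhibition, no conductance synapses, no synaptic plasticity, no
  spatial structure: the topology is the prototypical derangement-plus-
  extras graph.
* The latency responder is phenomenological; nothing in it models the
  biophysics of latency stretching.
* Network crossing times are step-quantized at 0.05 ms; microsecond-scale
  questions are addressed by the analysis-side interpolation operations,
  not by the engine.
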