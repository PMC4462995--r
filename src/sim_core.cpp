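#include <Rcpp.h>
#include <vector>
#include <utility>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Time-stepped network engine with delayed impulse deliveries and the
// history-dependent response-failure mechanism.
//
// Semantics per integration step (per neuron): accumulate all impulses due
// this step, apply the Euler leak factor (1 - dt/tau) once, then test the
// threshold once.  Because the voltage only changes at impulse arrivals and
// otherwise decays geometrically, the leak between events is applied lazily
// in closed form, (1 - dt/tau)^k, which is algebraically identical to eager
// per-step multiplication.  Threshold crossings can therefore only occur at
// steps where a neuron receives input, and only those neurons are examined.
//
// Failure draws use R's RNG, one uniform per threshold crossing, taken in
// ascending neuron-index order within a step, so runs are reproducible from
// set.seed() alone.
//
// Event kinds: 0 = stimulus, 1 = crossing, 2 = spike, 3 = failure.

// [[Rcpp::export(name = ".sim_core")]]
List sim_core(const int n,
              const IntegerVector edge_pre,    // 0-based presynaptic index
              const IntegerVector edge_post,   // 0-based postsynaptic index
              const NumericVector edge_w,      // dimensionless weight
              const IntegerVector edge_delay,  // delay in steps, >= 1
              const NumericVector tau_m,       // membrane constant, ms
              const NumericVector tau_c,       // critical period, ms
              const NumericVector alpha,       // forgetting exponent
              const IntegerVector stim_step,   // external stimuli, sorted
              const IntegerVector stim_neuron, // 0-based
              const NumericVector stim_w,
              const int n_steps,
              const double dt,
              const double extra_c,            // additional failure prob. C
              const double v_threshold,
              const double v_reset,
              const double v_fail,
              const int refr_steps,
              const double v0)
{
  const int n_edges = edge_pre.size();
  const int n_stim = stim_step.size();

  // CSR adjacency grouped by presynaptic neuron
  std::vector<int> ptr(n + 1, 0);
  for (int e = 0; e < n_edges; ++e) ptr[edge_pre[e] + 1]++;
  for (int i = 0; i < n; ++i) ptr[i + 1] += ptr[i];
  std::vector<int> adj_post(n_edges), adj_delay(n_edges);
  std::vector<double> adj_w(n_edges);
  {
    std::vector<int> fill(ptr.begin(), ptr.end() - 1);
    for (int e = 0; e < n_edges; ++e) {
      int p = fill[edge_pre[e]]++;
      adj_post[p] = edge_post[e];
      adj_w[p] = edge_w[e];
      adj_delay[p] = edge_delay[e];
    }
  }

  int max_delay = 1;
  for (int e = 0; e < n_edges; ++e)
    if (edge_delay[e] > max_delay) max_delay = edge_delay[e];
  const int ring = max_delay + 1;
  std::vector<std::vector<std::pair<int, double> > > bucket(ring);

  // per-neuron state
  std::vector<double> v(n, v0), s_num(n, 0.0), s_den(n, 0.0);
  std::vector<double> fct(n), ea(n), ea2(n);
  std::vector<int> upto(n, -1);      // v is valid as of the end of step upto[i]
  std::vector<int> refr_end(n, -1);  // first step accepting inputs again
  std::vector<int> ncross(n, 0), last_cross(n, 0);
  for (int i = 0; i < n; ++i) {
    fct[i] = 1.0 - dt / tau_m[i];
    ea[i] = std::exp(-alpha[i]);
    ea2[i] = ea[i] * ea[i];
  }

  std::vector<int> ev_step, ev_neuron, ev_kind;
  ev_step.reserve(65536);
  ev_neuron.reserve(65536);
  ev_kind.reserve(65536);

  std::vector<int> touched;
  std::vector<char> is_touched(n, 0);

  int sp = 0;
  for (int t = 0; t < n_steps; ++t) {
    std::vector<std::pair<int, double> >& b = bucket[t % ring];
    const bool has_ext = (sp < n_stim && stim_step[sp] == t);
    if (b.empty() && !has_ext) continue;

    touched.clear();

    // 1. accumulate all inputs due this step (refractory neurons discard)
    for (size_t q = 0; q < b.size(); ++q) {
      const int j = b[q].first;
      if (t < refr_end[j]) continue;
      if (upto[j] < t - 1) {
        v[j] *= std::pow(fct[j], (double)(t - 1 - upto[j]));
        upto[j] = t - 1;
      }
      v[j] += b[q].second;
      if (!is_touched[j]) { is_touched[j] = 1; touched.push_back(j); }
    }
    b.clear();
    while (sp < n_stim && stim_step[sp] == t) {
      const int j = stim_neuron[sp];
      ev_step.push_back(t); ev_neuron.push_back(j); ev_kind.push_back(0);
      if (t >= refr_end[j]) {
        if (upto[j] < t - 1) {
          v[j] *= std::pow(fct[j], (double)(t - 1 - upto[j]));
          upto[j] = t - 1;
        }
        v[j] += stim_w[sp];
        if (!is_touched[j]) { is_touched[j] = 1; touched.push_back(j); }
      }
      ++sp;
    }
    if (touched.empty()) continue;

    // 2. leak once, 3. single threshold test; neuron-index order fixes the
    // order of failure draws within a step
    std::sort(touched.begin(), touched.end());
    for (size_t q = 0; q < touched.size(); ++q) {
      const int j = touched[q];
      is_touched[j] = 0;
      v[j] *= fct[j];
      upto[j] = t;
      if (v[j] < v_threshold) continue;

      ev_step.push_back(t); ev_neuron.push_back(j); ev_kind.push_back(1);

      // append this crossing to the history first (the failure law sums
      // over all completed intervals, including the one ending now):
      // decay-and-add recursion
      if (ncross[j] >= 1) {
        const double gap = (t - last_cross[j]) * dt;
        s_num[j] = ea[j] * s_num[j] + (1.0 - gap / tau_c[j]) * ea2[j];
        s_den[j] = ea[j] * s_den[j] + ea2[j];
      }
      ncross[j] += 1;
      last_cross[j] = t;

      // failure probability: ratio of the accumulators, clamped to [0, 1];
      // zero before any interval is on record (the initial condition)
      double p = 0.0;
      if (ncross[j] >= 2 && s_den[j] > 0.0) {
        p = s_num[j] / s_den[j];
        if (p < 0.0) p = 0.0;
        else if (p > 1.0) p = 1.0;
      }
      p = extra_c + (1.0 - extra_c) * p;
      const double u = unif_rand();

      if (u < p) {  // response failure: no refractory period
        v[j] = v_fail;
        ev_step.push_back(t); ev_neuron.push_back(j); ev_kind.push_back(3);
      } else {      // evoked spike
        ev_step.push_back(t); ev_neuron.push_back(j); ev_kind.push_back(2);
        refr_end[j] = t + refr_steps;
        v[j] = v_reset;               // takes effect at the refractory end
        upto[j] = refr_end[j] - 1;
        for (int e = ptr[j]; e < ptr[j + 1]; ++e) {
          const int at = t + adj_delay[e];
          if (at < n_steps)
            bucket[at % ring].push_back(std::make_pair(adj_post[e], adj_w[e]));
        }
      }
    }
  }

  return List::create(_["step"] = wrap(ev_step),
                      _["neuron"] = wrap(ev_neuron),
                      _["kind"] = wrap(ev_kind));
}
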