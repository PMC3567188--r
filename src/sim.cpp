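// Spiking network simulator with conduction delays and online additive STDP.
//
// Event handling: a pre-synaptic somatic spike at step s reaches the synapse
// at s + d_axonal (where STDP pairing happens) and the post soma at
// s + d_axonal + d_dendritic (where it contributes EPSP drive). Delays are
// integer multiples of dt on a circular buffer.
//
// STDP bookkeeping: all-to-all pairing via two exponential somatic-spike
// traces per neuron plus a short recent-spike list used to correct the trace
// for pairs whose synaptic-time order differs from their somatic-time order
// (exact whenever d_dendritic <= d_axonal, which holds for every built
// network; for d_dendritic > d_axonal the few order-flipped pairs inside the
// |d_a - d_d| window are omitted).

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct RecentSpikes {
  // fixed-size ring of the most recent somatic spike steps
  static const int CAP = 16;
  int steps[CAP];
  int n = 0, head = 0;
  void push(int s) {
    steps[head] = s;
    head = (head + 1) % CAP;
    if (n < CAP) ++n;
  }
  // sum of exp(-(cur - s)*k) over recorded spikes with lo < s <= hi
  double expsum(int lo, int hi, int cur, double k) const {
    double out = 0.0;
    for (int i = 0; i < n; ++i) {
      int idx = (head - 1 - i + 2 * CAP) % CAP;
      int s = steps[idx];
      if (s <= lo) break;
      if (s <= hi) out += std::exp(-(double)(cur - s) * k);
    }
    return out;
  }
};

struct Trace {
  double val = 0.0;
  int step = 0;
  void decay_to(int cur, double k) {
    if (cur > step) {
      val *= std::exp(-(double)(cur - step) * k);
      step = cur;
    }
  }
};

} // namespace

// [[Rcpp::export]]
List cpp_simulate(
    int n_inputs, int n_neurons, int neuron_kind, // 0 = poisson, 1 = lif
    IntegerVector syn_pre,        // 0-based global id (inputs first)
    IntegerVector syn_post,       // 0-based neuron index
    NumericVector syn_weight,
    IntegerVector syn_da,         // axonal delay, steps
    IntegerVector syn_dd,         // dendritic delay, steps
    LogicalVector syn_plastic,
    NumericVector input_steps,    // input spike step (sorted ascending)
    IntegerVector input_ids,      // 0-based input index per spike
    double dt,                    // seconds
    int n_steps,
    double tau_rise, double tau_decay,            // seconds
    NumericVector lif_par,        // tau_m v_thresh v_rest v_reset e_syn refr_steps syn_gain
    bool plasticity_on,
    NumericVector stdp_par,       // eta c_pot c_dep tau_pot tau_dep(s) w_in w_out j_max
    int snapshot_every,           // steps; 0 = none
    bool record_spikes,
    double runaway_rate,          // spikes/s per neuron; <=0 disables
    int runaway_window) {         // steps

  const int n_syn = syn_pre.size();
  // fanout CSR over global pre ids
  const int n_nodes = n_inputs + n_neurons;
  std::vector<int> fan_cnt(n_nodes + 1, 0);
  for (int s = 0; s < n_syn; ++s) fan_cnt[syn_pre[s] + 1]++;
  for (int i = 0; i < n_nodes; ++i) fan_cnt[i + 1] += fan_cnt[i];
  std::vector<int> fan_idx(n_syn);
  {
    std::vector<int> cur(fan_cnt.begin(), fan_cnt.end() - 1);
    for (int s = 0; s < n_syn; ++s) fan_idx[cur[syn_pre[s]]++] = s;
  }
  // incoming plastic CSR over post neurons
  std::vector<int> in_cnt(n_neurons + 1, 0);
  for (int s = 0; s < n_syn; ++s)
    if (syn_plastic[s]) in_cnt[syn_post[s] + 1]++;
  for (int i = 0; i < n_neurons; ++i) in_cnt[i + 1] += in_cnt[i];
  std::vector<int> in_idx(in_cnt[n_neurons]);
  {
    std::vector<int> cur(in_cnt.begin(), in_cnt.end() - 1);
    for (int s = 0; s < n_syn; ++s)
      if (syn_plastic[s]) in_idx[cur[syn_post[s]]++] = s;
  }

  int max_delay = 1;
  for (int s = 0; s < n_syn; ++s) {
    if (syn_da[s] < 0 || syn_dd[s] < 0) stop("negative delay");
    if (syn_da[s] + syn_dd[s] > max_delay) max_delay = syn_da[s] + syn_dd[s];
  }
  const int H = max_delay + 2;

  std::vector<double> w(syn_weight.begin(), syn_weight.end());
  std::vector<double> drive_ring((size_t)n_neurons * H, 0.0);
  std::vector<std::vector<int>> event_ring(H); // plastic pre arrivals

  // synaptic filter state: unit-area double exponential
  const double a_dec = std::exp(-dt / tau_decay);
  const double b_dec = std::exp(-dt / tau_rise);
  const double norm = 1.0 / (tau_decay - tau_rise);
  std::vector<double> A(n_neurons, 0.0), B(n_neurons, 0.0);

  // LIF state
  const double tau_m = lif_par[0], v_th = lif_par[1], v_rest = lif_par[2],
               v_reset = lif_par[3], e_syn = lif_par[4];
  const int refr_steps = (int)lif_par[5];
  const double syn_gain = lif_par[6];
  std::vector<double> V(n_neurons, v_rest);
  std::vector<int> refr(n_neurons, 0);

  // STDP state
  const double eta = stdp_par[0], c_pot = stdp_par[1], c_dep = stdp_par[2];
  const double k_pot = dt / stdp_par[3], k_dep = dt / stdp_par[4];
  const double w_in = stdp_par[5], w_out = stdp_par[6], j_max = stdp_par[7];
  std::vector<Trace> trace_pot(n_neurons), trace_dep(n_neurons);
  std::vector<RecentSpikes> recent(n_neurons);

  // outputs
  std::vector<int> spk_step, spk_id;
  std::vector<int> step_counts(n_steps, 0);
  int n_snaps = snapshot_every > 0 ? n_steps / snapshot_every + 1 : 0;
  NumericMatrix snaps(n_snaps > 0 ? n_syn : 0, n_snaps);
  IntegerVector snap_steps(n_snaps);
  int snap_i = 0;

  double max_p = 0.0;
  bool runaway = false;
  int runaway_step = NA_INTEGER;
  long win_count = 0;

  RNGScope rng;
  int in_ptr = 0;
  const int n_in_spk = input_steps.size();

  auto deliver = [&](int syn, int cur) {
    // pre somatic spike delivered: schedule drive (and STDP event if plastic)
    if (syn_plastic[syn] && plasticity_on) {
      event_ring[(cur + syn_da[syn]) % H].push_back(syn);
    } else {
      int slot = (cur + syn_da[syn] + syn_dd[syn]) % H;
      drive_ring[(size_t)syn_post[syn] * H + slot] += w[syn];
    }
  };

  for (int cur = 0; cur < n_steps; ++cur) {
    if (snapshot_every > 0 && cur % snapshot_every == 0 && snap_i < n_snaps) {
      for (int s = 0; s < n_syn; ++s) snaps(s, snap_i) = w[s];
      snap_steps[snap_i++] = cur;
    }

    // (1) plastic pre arrivals scheduled for this step: STDP pre-side update,
    //     then EPSP drive at + d_dendritic
    {
      std::vector<int>& bucket = event_ring[cur % H];
      for (int syn : bucket) {
        int q = syn_post[syn];
        // depression from past post synaptic events, plus per-pre-spike term
        trace_dep[q].decay_to(cur, k_dep);
        double td = trace_dep[q].val;
        double pot_extra = 0.0;
        if (syn_dd[syn] > 0) {
          // post somatic spikes in the last d_dendritic window have synaptic
          // events after this pre arrival: they potentiate, not depress
          td -= recent[q].expsum(cur - syn_dd[syn], cur, cur, k_dep);
          if (td < 0) td = 0;
          td *= std::exp((double)syn_dd[syn] * k_dep);
          pot_extra = std::exp(-(double)syn_dd[syn] * k_pot) *
                      recent[q].expsum(cur - syn_dd[syn], cur, cur, -k_pot);
        }
        double dw = eta * (w_in - c_dep * td + c_pot * pot_extra);
        w[syn] += dw;
        if (w[syn] < 0) w[syn] = 0; else if (w[syn] > j_max) w[syn] = j_max;
        int slot = (cur + syn_dd[syn]) % H;
        drive_ring[(size_t)q * H + slot] += w[syn];
      }
      bucket.clear();
    }

    // (2) external input spikes at this step
    while (in_ptr < n_in_spk && (int)input_steps[in_ptr] == cur) {
      int g = input_ids[in_ptr];
      for (int k = fan_cnt[g]; k < fan_cnt[g + 1]; ++k)
        deliver(fan_idx[k], cur);
      ++in_ptr;
    }

    // (3) integrate synaptic filters and neuron dynamics, emit spikes
    for (int i = 0; i < n_neurons; ++i) {
      A[i] *= a_dec; B[i] *= b_dec;
      double inc = drive_ring[(size_t)i * H + (cur % H)];
      if (inc != 0.0) {
        A[i] += inc; B[i] += inc;
        drive_ring[(size_t)i * H + (cur % H)] = 0.0;
      }
      double drive = (A[i] - B[i]) * norm; // 1/s
      bool fired = false;
      if (neuron_kind == 0) {
        double p = drive * dt;
        if (p > max_p) max_p = p;
        if (p > 0 && unif_rand() < p) fired = true;
      } else {
        if (refr[i] > 0) {
          --refr[i];
        } else {
          V[i] += dt * ((v_rest - V[i]) / tau_m +
                        syn_gain * drive * (e_syn - V[i]));
          if (V[i] >= v_th) {
            fired = true;
            V[i] = v_reset;
            refr[i] = refr_steps;
          }
        }
      }
      if (fired) {
        step_counts[cur]++;
        if (record_spikes) { spk_step.push_back(cur); spk_id.push_back(i); }
        // (3a) post-side STDP on incoming plastic synapses
        if (plasticity_on && in_cnt[i + 1] > in_cnt[i]) {
          trace_pot[i].decay_to(cur, k_pot); // ensure own traces fresh later
          for (int k = in_cnt[i]; k < in_cnt[i + 1]; ++k) {
            int syn = in_idx[k];
            int p = syn_pre[syn];
            double tp;
            int deff = syn_da[syn] - syn_dd[syn];
            if (p < n_inputs) {
              tp = 0.0; // inputs are never plastic pre-sources
            } else {
              int pn = p - n_inputs;
              trace_pot[pn].decay_to(cur, k_pot);
              tp = trace_pot[pn].val;
              if (deff > 0) {
                // pre spikes in the last d_eff window reach the synapse after
                // this post event; they pair on the pre-arrival side instead
                tp -= recent[pn].expsum(cur - deff, cur, cur, k_pot);
                if (tp < 0) tp = 0;
              }
              tp *= std::exp((double)deff * k_pot);
            }
            double dw = eta * (w_out + c_pot * tp);
            w[syn] += dw;
            if (w[syn] < 0) w[syn] = 0;
            else if (w[syn] > j_max) w[syn] = j_max;
          }
        }
        // (3b) propagate to targets
        int g = n_inputs + i;
        for (int k = fan_cnt[g]; k < fan_cnt[g + 1]; ++k)
          deliver(fan_idx[k], cur);
        // (3c) update somatic traces and recent list (after pairing, so a
        //      simultaneous pre/post pair takes the potentiation branch once)
        if (plasticity_on) {
          trace_pot[i].decay_to(cur, k_pot);
          trace_dep[i].decay_to(cur, k_dep);
          trace_pot[i].val += 1.0;
          trace_dep[i].val += 1.0;
          recent[i].push(cur);
        }
      }
    }

    // (4) runaway check on a sliding window
    if (runaway_rate > 0) {
      win_count += step_counts[cur];
      if (cur >= runaway_window) win_count -= step_counts[cur - runaway_window];
      if (cur >= runaway_window) {
        double rate = (double)win_count /
                      (n_neurons * runaway_window * dt);
        if (rate > runaway_rate) {
          runaway = true;
          runaway_step = cur;
          break;
        }
      }
    }
  }

  if (snapshot_every > 0 && snap_i < n_snaps) {
    for (int s = 0; s < n_syn; ++s) snaps(s, snap_i) = w[s];
    snap_steps[snap_i++] = n_steps;
  }

  return List::create(
      _["spike_step"] = IntegerVector(spk_step.begin(), spk_step.end()),
      _["spike_id"] = IntegerVector(spk_id.begin(), spk_id.end()),
      _["weights"] = NumericVector(w.begin(), w.end()),
      _["step_counts"] = IntegerVector(step_counts.begin(), step_counts.end()),
      _["snapshots"] = snaps,
      _["snapshot_steps"] = snap_steps,
      _["n_snapshots"] = snap_i,
      _["max_poisson_p"] = max_p,
      _["runaway"] = runaway,
      _["runaway_step"] = runaway_step);
}

// [[Rcpp::export]]
IntegerVector cpp_crosscorr_counts(NumericVector ta, NumericVector tb,
                                   double bin, int n_half,
                                   bool exclude_zero) {
  // counts of (tb - ta) in bins centered on k*bin, k = -n_half..n_half
  int nb = 2 * n_half + 1;
  IntegerVector counts(nb);
  double max_lag = (n_half + 0.5) * bin;
  int j_lo = 0;
  for (int i = 0; i < ta.size(); ++i) {
    double t = ta[i];
    while (j_lo < tb.size() && tb[j_lo] < t - max_lag) ++j_lo;
    for (int j = j_lo; j < tb.size() && tb[j] < t + max_lag; ++j) {
      double lag = tb[j] - t;
      if (exclude_zero && lag == 0.0) continue;
      int k = (int)std::lround(lag / bin);
      if (k >= -n_half && k <= n_half) counts[k + n_half]++;
    }
  }
  return counts;
}
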