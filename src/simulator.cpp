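#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Nearest-neighbour anticausal STDP accumulation: for each presynaptic spike
// inside the window, pair it with the latest postsynaptic spike strictly
// before it (also inside the window) and sum eta * exp((t_post - t_pre)/tau).
// Both spike vectors must be sorted ascending.
static double nn_anticausal_sum(const std::vector<double>& pre,
                                const std::vector<double>& post,
                                double eta, double tau) {
  if (pre.empty() || post.empty()) return 0.0;
  double f = 0.0;
  size_t k = 0;
  for (size_t p = 0; p < pre.size(); ++p) {
    while (k < post.size() && post[k] < pre[p]) ++k;
    if (k > 0) f += eta * std::exp((post[k - 1] - pre[p]) / tau);
  }
  return f;
}

// [[Rcpp::export]]
double cpp_stdp_kernel_sum(NumericVector pre, NumericVector post,
                           double eta, double tau) {
  std::vector<double> pr(pre.begin(), pre.end());
  std::vector<double> po(post.begin(), post.end());
  return nn_anticausal_sum(pr, po, eta, tau);
}

struct Event { int unit; bool stim; };

// Clock-driven exponential-Euler integrator for the current-based LIF network
// with delta-current synapses, synaptic delay, refractory clamping, and the
// homeostatic plasticity rule (drift + anticausal STDP + biased uniform noise)
// applied synchronously every T_update using spikes from [t - T_update, t).
//
// w(i, j): weight of the synapse from source i to target j (>= 0).
// ext(i, j) = 1: the synapse listens to stimulus channel i, else to neuron i.
// inh(i, j) = 1: delivered current is negative (inhibitory synapse).
// Neuron parameters are per-neuron vectors so heterogeneous (hardware-like)
// parameter sets use the same code path as the idealized model.
// [[Rcpp::export]]
List cpp_simulate(int N, double duration, double dt,
                  NumericMatrix w0, IntegerMatrix ext, IntegerMatrix inh,
                  NumericVector stim_time, IntegerVector stim_unit,
                  NumericVector u_thresh, NumericVector u_leak,
                  NumericVector u_reset, NumericVector tau_mem,
                  NumericVector tau_ref, NumericVector tau_exc,
                  NumericVector tau_inh,
                  double d_syn, double gamma_v,
                  bool plasticity,
                  double lambda_stdp, double lambda_drift,
                  double eta_stdp, double tau_stdp,
                  double n_amp, double n_mean, double T_update,
                  double snapshot_every, bool record_u) {
  const int S = (int) std::ceil(duration / dt - 1e-9);
  const int delay_steps = std::max(1, (int) std::lround(d_syn / dt));
  const int upd_steps = std::max(1, (int) std::lround(T_update / dt));

  NumericMatrix w = clone(w0);

  std::vector<double> u(N), Ie(N, 0.0), Ii(N, 0.0);
  // refractoriness handled on the step grid (tau_ref rounded to steps) so
  // that release times are exact integers, not float comparisons
  std::vector<int> release_step(N, -1), refrac_steps(N);
  std::vector<double> am(N), ae(N), ai(N), om(N);
  for (int j = 0; j < N; ++j) {
    u[j] = u_leak[j];
    am[j] = std::exp(-dt / tau_mem[j]);
    om[j] = 1.0 - am[j];
    ae[j] = std::exp(-dt / tau_exc[j]);
    ai[j] = std::exp(-dt / tau_inh[j]);
    refrac_steps[j] = (int) std::lround(tau_ref[j] / dt);
  }

  const int R = delay_steps + 1;
  std::vector< std::vector<Event> > ring(R);

  // plasticity spike windows (cleared after every update)
  std::vector< std::vector<double> > net_win(N), stim_win(N);

  std::vector<double> sp_time; std::vector<int> sp_unit;
  sp_time.reserve(100000); sp_unit.reserve(100000);

  // weight trajectory (mean weight at every plasticity update)
  std::vector<double> traj_t, traj_w;
  // full-matrix snapshots
  const int snap_steps = snapshot_every > 0
    ? std::max(1, (int) std::lround(snapshot_every / dt)) : 0;
  List snaps; std::vector<double> snap_t;

  NumericMatrix utrace;
  if (record_u) utrace = NumericMatrix(N, S);

  int sp = 0; // stimulus pointer
  const int n_stim = stim_time.size();

  for (int s = 0; s < S; ++s) {
    const double t = s * dt;

    // synchronous plasticity on window [t - T_update, t)
    if (plasticity && s > 0 && s % upd_steps == 0) {
      double wsum = 0.0;
      for (int j = 0; j < N; ++j) {
        for (int i = 0; i < N; ++i) {
          const std::vector<double>& pre = ext(i, j) ? stim_win[i] : net_win[i];
          double f = nn_anticausal_sum(pre, net_win[j], eta_stdp, tau_stdp);
          double noise = R::runif(-n_amp, n_amp) + n_mean;
          double wn = w(i, j) - lambda_stdp * f - lambda_drift * w(i, j) + noise;
          w(i, j) = wn > 0.0 ? wn : 0.0;
          wsum += w(i, j);
        }
      }
      for (int i = 0; i < N; ++i) { net_win[i].clear(); stim_win[i].clear(); }
      traj_t.push_back(t);
      traj_w.push_back(wsum / ((double) N * N));
    }

    if (snap_steps > 0 && s % snap_steps == 0) {
      snaps.push_back(clone(w));
      snap_t.push_back(t);
    }

    // queue stimulus events emitted during [t, t + dt)
    while (sp < n_stim && stim_time[sp] < t + dt) {
      int slot = (s + delay_steps) % R;
      ring[slot].push_back(Event{ stim_unit[sp] - 1, true });
      if (plasticity) stim_win[stim_unit[sp] - 1].push_back(stim_time[sp]);
      ++sp;
    }

    // deliver events due now
    std::vector<Event>& due = ring[s % R];
    for (size_t e = 0; e < due.size(); ++e) {
      const int i = due[e].unit;
      const bool st = due[e].stim;
      for (int j = 0; j < N; ++j) {
        if ((ext(i, j) != 0) == st) {
          const double amt = gamma_v * w(i, j);
          if (amt != 0.0) {
            if (inh(i, j)) Ii[j] -= amt; else Ie[j] += amt;
          }
        }
      }
    }
    due.clear();

    // integrate membranes (exponential Euler; I held constant over the step),
    // decay currents, test thresholds
    const double tn = t + dt;
    for (int j = 0; j < N; ++j) {
      const bool free = s >= release_step[j];
      if (free) {
        u[j] = u_leak[j] + (u[j] - u_leak[j]) * am[j] + (Ie[j] + Ii[j]) * om[j];
      } else {
        u[j] = u_reset[j];
      }
      Ie[j] *= ae[j];
      Ii[j] *= ai[j];
      if (free && u[j] >= u_thresh[j]) {
        sp_time.push_back(tn);
        sp_unit.push_back(j + 1);
        u[j] = u_reset[j];
        release_step[j] = s + refrac_steps[j] + 1;
        int slot = (s + 1 + delay_steps) % R;
        // guard: events scheduled at s+1+delay may collide with slot processed
        // at step s+1 only if ring shorter than needed; R = delay+1 is exact.
        ring[slot % R].push_back(Event{ j, false });
        if (plasticity) net_win[j].push_back(tn);
      }
      if (record_u) utrace(j, s) = u[j];
    }

    if ((s & 0x3FFF) == 0) {
      for (int j = 0; j < N; ++j)
        if (!std::isfinite(u[j]))
          stop("non-finite membrane potential: integration error");
    }
  }

  List out = List::create(
    _["spike_time"] = wrap(sp_time),
    _["spike_unit"] = wrap(sp_unit),
    _["w_final"] = w,
    _["traj_time"] = wrap(traj_t),
    _["traj_mean_w"] = wrap(traj_w),
    _["snapshots"] = snaps,
    _["snapshot_time"] = wrap(snap_t));
  if (record_u) out["u_trace"] = utrace;
  return out;
}
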