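#include <Rcpp.h>
using namespace Rcpp;

// Exact stochastic simulation (Gillespie direct method) of one trajectory
// on a reaction network with a fixed, small state space.
//
// trans_from/trans_to: 0-based state indices of directed transitions
// trans_rate: propensity of each transition (constant; pseudo-first-order
//   bath for the bimolecular steps)
// bound: per-state flag, true when the state is any non-empty configuration
// Returns the time-weighted fraction of [burn_in, t_end] spent in bound
// states, the number of steps taken, and the time actually covered (the
// trajectory stops early if max_steps is exhausted; the average then runs
// over [burn_in, t_reached]).
//
// Uses R's RNG so that set.seed() in R makes trajectories reproducible.
// [[Rcpp::export]]
List ssa_bound_fraction(IntegerVector trans_from, IntegerVector trans_to,
                        NumericVector trans_rate, LogicalVector bound,
                        int n_states, int start_state, double t_end,
                        double burn_in, double max_steps) {
  int n_trans = trans_from.size();
  // index transitions by source state
  std::vector<std::vector<int>> out(n_states);
  std::vector<double> total(n_states, 0.0);
  for (int k = 0; k < n_trans; ++k) {
    out[trans_from[k]].push_back(k);
    total[trans_from[k]] += trans_rate[k];
  }
  RNGScope rngScope;
  int s = start_state;
  double t = 0.0, t_bound = 0.0;
  double steps = 0.0;
  while (t < t_end && steps < max_steps) {
    double tot = total[s];
    double dt = tot > 0 ? R::rexp(1.0 / tot) : (t_end - t);
    double t_next = std::min(t + dt, t_end);
    if (t_next > burn_in && bound[s]) {
      double lo = std::max(t, burn_in);
      t_bound += t_next - lo;
    }
    t = t + dt;
    if (t >= t_end || tot <= 0) break;
    // pick the firing transition
    double u = unif_rand() * tot;
    double acc = 0.0;
    int chosen = out[s].back();
    for (size_t m = 0; m < out[s].size(); ++m) {
      acc += trans_rate[out[s][m]];
      if (u <= acc) { chosen = out[s][m]; break; }
    }
    s = trans_to[chosen];
    steps += 1.0;
  }
  double t_reached = std::min(t, t_end);
  double window = t_reached - burn_in;
  double bf = window > 0 ? t_bound / window : NA_REAL;
  return List::create(_["bound_fraction"] = bf,
                      _["steps"] = steps,
                      _["t_reached"] = t_reached);
}
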