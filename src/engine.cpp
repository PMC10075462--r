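// Discrete-time step kernel for the queen-patrol agent-based model.
// One step executes, in fixed order: (1) phase flips for expired timers,
// (2) random-walk moves of active agents in a freshly shuffled order,
// (3) queen-worker contact detection then worker-worker pair counting,
// (4) synchronous internal-state updates from pre-step values,
// (5) logging, (6) timer decrement.
// All randomness comes from R's global RNG stream (RNGScope), so trials are
// reproducible from set.seed() alone.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline int runif_int(int n) {
  // uniform integer in [0, n)
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

static inline int rest_steps(double iq, double trconst, double delta) {
  double tr = trconst * std::exp(-delta * iq);
  long r = (long)std::floor(tr + 0.5);  // round half away from zero
  return r < 1 ? 1 : (int)r;
}

// [[Rcpp::export]]
List sim_steps_cpp(List world, List par, int max_steps, bool until_all,
                   bool record_states, int state_stride) {
  RNGScope scope;

  // parameters (beta/gamma already have the rate multiplier applied)
  const int    trconst  = as<int>(par["trconstant"]);
  const int    taconst  = as<int>(par["taconstant"]);
  const double delta    = as<double>(par["delta"]);
  const double eps      = as<double>(par["epsilon"]);
  const double alpha    = as<double>(par["alpha"]);
  const double beta     = as<double>(par["beta"]);
  const double gamma    = as<double>(par["gamma"]);
  const double kappa    = as<double>(par["kappa"]);
  const bool   feedback = as<bool>(par["feedback_enabled"]);
  const bool   cheb     = as<bool>(par["chebyshev"]);

  // world state (copied; the input list is left untouched)
  const int C = as<int>(world["side_cells"]);
  int qx = as<int>(world["qx"]), qy = as<int>(world["qy"]);
  bool q_active = as<bool>(world["q_active"]);
  int q_timer = as<int>(world["q_timer"]);
  IntegerVector wx = clone(as<IntegerVector>(world["wx"]));
  IntegerVector wy = clone(as<IntegerVector>(world["wy"]));
  LogicalVector w_active = clone(as<LogicalVector>(world["w_active"]));
  IntegerVector w_timer = clone(as<IntegerVector>(world["w_timer"]));
  double iq = as<double>(world["iq"]);
  NumericVector iw = clone(as<NumericVector>(world["iw"]));
  int last_contacted = as<int>(world["last_contacted"]);  // 1..N or 0
  LogicalVector contacted = clone(as<LogicalVector>(world["contacted"]));
  IntegerVector contact_counts =
    clone(as<IntegerVector>(world["contact_counts"]));
  int step = as<int>(world["step"]);
  const int N = wx.size();

  // occupancy: 0 empty, 1 queen, j+1 worker j (1-based worker index)
  std::vector<int> occ((size_t)C * C, 0);
  occ[qx + qy * C] = 1;
  for (int j = 0; j < N; ++j) occ[wx[j] + wy[j] * C] = j + 2;

  int n_contacted = 0;
  for (int j = 0; j < N; ++j) if (contacted[j]) ++n_contacted;

  const int n_off = cheb ? 8 : 4;
  const int offx[8] = {0, 0, 1, -1, 1, 1, -1, -1};
  const int offy[8] = {1, -1, 0, 0, 1, -1, 1, -1};
  // forward offsets for once-per-pair worker-worker counting
  const int n_f = cheb ? 4 : 2;
  const int fox[4] = {1, 0, 1, 1};
  const int foy[4] = {0, 1, 1, -1};

  std::vector<double> log_iq, log_meaniw;
  std::vector<int> log_qact, log_ww;
  std::vector<int> ev_step, ev_worker, ev_qact;
  std::vector<double> ev_iw_before;
  std::vector<double> states;
  std::vector<int> state_steps;
  std::vector<int> order(N + 1);

  bool terminated = (until_all && n_contacted == N);
  int steps_run = 0;

  while (!terminated && steps_run < max_steps) {
    ++step; ++steps_run;

    // (1) phase flips
    if (q_timer == 0) {
      q_active = !q_active;
      q_timer = q_active ? taconst : rest_steps(iq, trconst, delta);
    }
    for (int j = 0; j < N; ++j) {
      if (w_timer[j] == 0) {
        w_active[j] = !w_active[j];
        w_timer[j] = w_active[j] ? taconst : trconst;
      }
    }

    // (2) movement of active agents, shuffled order (0 = queen, j = worker j)
    int m = 0;
    if (q_active) order[m++] = 0;
    for (int j = 0; j < N; ++j) if (w_active[j]) order[m++] = j + 1;
    for (int i = m - 1; i > 0; --i) {
      int k = runif_int(i + 1);
      int tmp = order[i]; order[i] = order[k]; order[k] = tmp;
    }
    for (int i = 0; i < m; ++i) {
      int a = order[i];
      int x = (a == 0) ? qx : wx[a - 1];
      int y = (a == 0) ? qy : wy[a - 1];
      int d = runif_int(4);  // 0=N(+y) 1=S(-y) 2=E(+x) 3=W(-x)
      int dx = (d == 2) ? 1 : (d == 3 ? -1 : 0);
      int dy = (d == 0) ? 1 : (d == 1 ? -1 : 0);
      int tx = x + dx, ty = y + dy;
      if (tx >= 0 && ty >= 0 && tx < C && ty < C && occ[tx + ty * C] == 0) {
        occ[x + y * C] = 0;
        occ[tx + ty * C] = (a == 0) ? 1 : a + 1;
        if (a == 0) { qx = tx; qy = ty; }
        else { wx[a - 1] = tx; wy[a - 1] = ty; }
      }
    }

    // (3) contact detection: queen first, then worker-worker pair count
    int cw = 0;  // contacted worker, 1..N, 0 = none
    {
      int elig[8]; int k = 0;
      for (int o = 0; o < n_off; ++o) {
        int tx = qx + offx[o], ty = qy + offy[o];
        if (tx < 0 || ty < 0 || tx >= C || ty >= C) continue;
        int v = occ[tx + ty * C];
        if (v >= 2 && v - 1 != last_contacted) elig[k++] = v - 1;
      }
      if (k == 1) cw = elig[0];
      else if (k > 1) cw = elig[runif_int(k)];
    }
    int ww = 0;
    for (int j = 0; j < N; ++j) {
      for (int o = 0; o < n_f; ++o) {
        int tx = wx[j] + fox[o], ty = wy[j] + foy[o];
        if (tx < 0 || ty < 0 || tx >= C || ty >= C) continue;
        if (occ[tx + ty * C] >= 2) ++ww;
      }
    }

    // (4) synchronous state updates from pre-step values
    double iw_pre_c = (cw > 0) ? iw[cw - 1] : 0.0;
    for (int j = 0; j < N; ++j) {
      double coef = 1.0 - beta;
      if (cw == j + 1 && feedback) coef -= kappa;
      iw[j] = coef * iw[j] + gamma;
    }
    iq = (1.0 - eps) * iq + ((cw > 0) ? alpha * iw_pre_c : 0.0);
    if (cw > 0) {
      last_contacted = cw;
      ++contact_counts[cw - 1];
      if (!contacted[cw - 1]) { contacted[cw - 1] = true; ++n_contacted; }
      ev_step.push_back(step);
      ev_worker.push_back(cw);
      ev_qact.push_back(q_active ? 1 : 0);
      ev_iw_before.push_back(iw_pre_c);
    }

    // (5) logging
    double s = 0.0;
    for (int j = 0; j < N; ++j) s += iw[j];
    log_iq.push_back(iq);
    log_qact.push_back(q_active ? 1 : 0);
    log_meaniw.push_back(s / N);
    log_ww.push_back(ww);
    if (record_states && (step % state_stride == 0)) {
      state_steps.push_back(step);
      for (int j = 0; j < N; ++j) states.push_back(iw[j]);
    }

    // (6) timer decrement
    --q_timer;
    for (int j = 0; j < N; ++j) --w_timer[j];

    if (until_all && n_contacted == N) terminated = true;
  }

  NumericMatrix smat(record_states ? (int)state_steps.size() : 0, N);
  for (size_t r = 0; r < state_steps.size(); ++r)
    for (int j = 0; j < N; ++j) smat((int)r, j) = states[r * N + j];

  return List::create(
    _["qx"] = qx, _["qy"] = qy, _["q_active"] = q_active,
    _["q_timer"] = q_timer,
    _["wx"] = wx, _["wy"] = wy, _["w_active"] = w_active,
    _["w_timer"] = w_timer,
    _["iq"] = iq, _["iw"] = iw,
    _["last_contacted"] = last_contacted,
    _["contacted"] = contacted, _["n_contacted"] = n_contacted,
    _["contact_counts"] = contact_counts,
    _["step"] = step, _["steps_run"] = steps_run,
    _["terminated"] = terminated,
    _["log_iq"] = wrap(log_iq), _["log_qact"] = wrap(log_qact),
    _["log_meaniw"] = wrap(log_meaniw), _["log_ww"] = wrap(log_ww),
    _["ev_step"] = wrap(ev_step), _["ev_worker"] = wrap(ev_worker),
    _["ev_qact"] = wrap(ev_qact), _["ev_iw_before"] = wrap(ev_iw_before),
    _["states"] = smat, _["state_steps"] = wrap(state_steps));
}
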