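#include <Rcpp.h>
#include "bc_rng.h"
using namespace Rcpp;

// Boolean rules are compiled (in R) to reverse-Polish programs over the
// state vector.  Opcodes: k >= 1 pushes state[k-1]; -1 AND; -2 OR; -3 NOT;
// -4 pushes TRUE; -5 pushes FALSE.

static inline bool eval_rpn(const int *code, int len, const int *state) {
  bool stack[64];
  int sp = 0;
  for (int i = 0; i < len; ++i) {
    int op = code[i];
    if (op >= 1) {
      stack[sp++] = state[op - 1] != 0;
    } else if (op == -1) {
      bool b = stack[--sp];
      stack[sp - 1] = stack[sp - 1] && b;
    } else if (op == -2) {
      bool b = stack[--sp];
      stack[sp - 1] = stack[sp - 1] || b;
    } else if (op == -3) {
      stack[sp - 1] = !stack[sp - 1];
    } else if (op == -4) {
      stack[sp++] = true;
    } else {
      stack[sp++] = false;
    }
  }
  return stack[0];
}

struct NetView {
  const int *code;
  const int *off;   // 0-based offsets into code
  const int *len;
  const double *up;
  const double *down;
  const int *input; // 1 if pinned input node
  int n;
};

// Rates at or above BC_FORCE_RATE act unconditionally (not gated by the
// node's logic): over-expression / knockout overrides clamp a node by sheer
// mass action, as in MaBoSS-style ungated rate expressions.
#define BC_FORCE_RATE 1e5

static inline double node_rate(const NetView &nv, const int *state, int j) {
  if (nv.input[j]) return 0.0;
  if (state[j] == 0 && nv.up[j] >= BC_FORCE_RATE) return nv.up[j];
  if (state[j] == 1 && nv.down[j] >= BC_FORCE_RATE) return nv.down[j];
  bool target = eval_rpn(nv.code + nv.off[j], nv.len[j], state);
  if (target && state[j] == 0) return nv.up[j];
  if (!target && state[j] == 1) return nv.down[j];
  return 0.0;
}

// one Gillespie step; state modified in place; returns waiting time
static double gillespie_one(const NetView &nv, int *state, BCRng &rng,
                            double *rates /* scratch length n */) {
  double total = 0.0;
  for (int j = 0; j < nv.n; ++j) {
    rates[j] = node_rate(nv, state, j);
    total += rates[j];
  }
  if (total <= 0.0) return R_PosInf;
  double wait = rng.exp_rand(total);
  double u = rng.unif() * total;
  double acc = 0.0;
  int pick = nv.n - 1;
  for (int j = 0; j < nv.n; ++j) {
    acc += rates[j];
    if (u < acc) { pick = j; break; }
  }
  state[pick] = 1 - state[pick];
  return wait;
}

// advance one trajectory over a time window; returns elapsed-at-exit times
// for tracked nodes if track != NULL
static void advance_traj(const NetView &nv, int *state, double window,
                         BCRng &rng, double *rates,
                         const int *track, int ntrack, double *first_time) {
  double t = 0.0;
  std::vector<int> trial(nv.n);
  while (true) {
    std::copy(state, state + nv.n, trial.begin());
    double wait = gillespie_one(nv, trial.data(), rng, rates);
    if (!R_FINITE(wait) || t + wait > window) break;
    t += wait;
    std::copy(trial.begin(), trial.end(), state);
    if (track) {
      for (int m = 0; m < ntrack; ++m) {
        int j = track[m];
        if (state[j] == 1 && !R_FINITE(first_time[m]) ) first_time[m] = t;
      }
    }
  }
}

static NetView make_view(const IntegerVector &code, const IntegerVector &off,
                         const IntegerVector &len, const NumericVector &up,
                         const NumericVector &down, const IntegerVector &input) {
  NetView nv;
  nv.code = code.begin(); nv.off = off.begin(); nv.len = len.begin();
  nv.up = up.begin(); nv.down = down.begin(); nv.input = input.begin();
  nv.n = up.size();
  return nv;
}

// [[Rcpp::export]]
LogicalVector cpp_eval_logic(IntegerVector code, IntegerVector off,
                             IntegerVector len, IntegerVector state) {
  int n = off.size();
  LogicalVector out(n);
  for (int j = 0; j < n; ++j)
    out[j] = eval_rpn(code.begin() + off[j], len[j], state.begin());
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_transition_rates(IntegerVector code, IntegerVector off,
                                   IntegerVector len, NumericVector up,
                                   NumericVector down, IntegerVector input,
                                   IntegerVector state) {
  NetView nv = make_view(code, off, len, up, down, input);
  NumericVector out(nv.n);
  for (int j = 0; j < nv.n; ++j) out[j] = node_rate(nv, state.begin(), j);
  return out;
}

// [[Rcpp::export]]
List cpp_gillespie_step(IntegerVector code, IntegerVector off, IntegerVector len,
                        NumericVector up, NumericVector down, IntegerVector input,
                        IntegerVector state, IntegerVector rng_state) {
  NetView nv = make_view(code, off, len, up, down, input);
  BCRng rng = bc_load(rng_state.begin());
  IntegerVector s = clone(state);
  std::vector<double> rates(nv.n);
  double wait = gillespie_one(nv, s.begin(), rng, rates.data());
  if (!R_FINITE(wait)) s = clone(state); // absorbing: unchanged
  bc_store(rng, rng_state.begin());
  return List::create(_["state"] = s, _["wait"] = wait);
}

// [[Rcpp::export]]
IntegerVector cpp_advance(IntegerVector code, IntegerVector off, IntegerVector len,
                          NumericVector up, NumericVector down, IntegerVector input,
                          IntegerVector state, double window,
                          IntegerVector rng_state) {
  NetView nv = make_view(code, off, len, up, down, input);
  BCRng rng = bc_load(rng_state.begin());
  IntegerVector s = clone(state);
  std::vector<double> rates(nv.n);
  advance_traj(nv, s.begin(), window, rng, rates.data(), NULL, 0, NULL);
  bc_store(rng, rng_state.begin());
  return s;
}

// n independent trajectories: per-trajectory streams derived from seed so the
// ensemble is reproducible and embarrassingly order-independent.
// init_probs: per-node Bernoulli P(node = 1) at t = 0.
// track: 0-based node indices whose first-activation times are recorded.
// [[Rcpp::export]]
List cpp_ensemble(IntegerVector code, IntegerVector off, IntegerVector len,
                  NumericVector up, NumericVector down, IntegerVector input,
                  NumericVector init_probs, double horizon, int n, double seed,
                  IntegerVector track) {
  NetView nv = make_view(code, off, len, up, down, input);
  int k = nv.n, ntrack = track.size();
  IntegerMatrix finals(n, k);
  NumericMatrix first_times(n, ntrack);
  std::vector<double> rates(k);
  std::vector<int> state(k);
  std::vector<double> ft(ntrack);
  for (int i = 0; i < n; ++i) {
    BCRng rng;
    rng.seed_from((uint64_t)seed, (uint64_t)i + 1ULL);
    for (int j = 0; j < k; ++j)
      state[j] = (rng.unif() < init_probs[j]) ? 1 : 0;
    for (int m = 0; m < ntrack; ++m)
      ft[m] = (state[track[m]] == 1) ? 0.0 : R_PosInf;
    advance_traj(nv, state.data(), horizon, rng, rates.data(),
                 ntrack ? track.begin() : NULL, ntrack, ft.data());
    for (int j = 0; j < k; ++j) finals(i, j) = state[j];
    for (int m = 0; m < ntrack; ++m) first_times(i, m) = ft[m];
  }
  return List::create(_["final_states"] = finals, _["first_times"] = first_times);
}

// advance the networks of many cell agents in place.
// states: cells x nodes integer matrix; rng: cells x 4 integer matrix;
// rows: 1-based row indices of the cells due for an update.
// track_node: 0-based node index (-1 = none); the returned logical vector
// marks cells whose tracked node was active at any event inside the window
// (so sub-step transients are not missed).
// [[Rcpp::export]]
LogicalVector cpp_advance_cells(IntegerVector code, IntegerVector off,
                                IntegerVector len, NumericVector up,
                                NumericVector down, IntegerVector input,
                                IntegerMatrix states, IntegerMatrix rng,
                                IntegerVector rows, double window,
                                int track_node) {
  NetView nv = make_view(code, off, len, up, down, input);
  int k = nv.n;
  std::vector<double> rates(k);
  std::vector<int> state(k);
  int rs[4];
  LogicalVector ever(rows.size());
  int track[1];
  double ft[1];
  if (track_node >= 0) track[0] = track_node;
  for (int ii = 0; ii < rows.size(); ++ii) {
    int i = rows[ii] - 1;
    for (int j = 0; j < k; ++j) state[j] = states(i, j);
    for (int m = 0; m < 4; ++m) rs[m] = rng(i, m);
    BCRng r = bc_load(rs);
    if (track_node >= 0) {
      ft[0] = (state[track_node] == 1) ? 0.0 : R_PosInf;
      advance_traj(nv, state.data(), window, r, rates.data(), track, 1, ft);
      ever[ii] = R_FINITE(ft[0]);
    } else {
      advance_traj(nv, state.data(), window, r, rates.data(), NULL, 0, NULL);
      ever[ii] = false;
    }
    bc_store(r, rs);
    for (int j = 0; j < k; ++j) states(i, j) = state[j];
    for (int m = 0; m < 4; ++m) rng(i, m) = rs[m];
  }
  return ever;
}

// [[Rcpp::export]]
IntegerVector cpp_rng_new(double seed, double id) {
  BCRng r;
  r.seed_from((uint64_t)seed, (uint64_t)id);
  IntegerVector out(4);
  bc_store(r, out.begin());
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_rng_unif(IntegerVector rng_state, int n) {
  BCRng r = bc_load(rng_state.begin());
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = r.unif();
  bc_store(r, rng_state.begin());
  return out;
}
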