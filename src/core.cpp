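// Compiled cores for teacher-forced likelihood replay, value-iteration
// planning, and closed-loop simulation. Cell indexing and action coding
// mirror the R side: cell index = x + y*W + 1 (x east, y north, 0-based),
// actions 1..4 = N,E,S,W with N=(0,+1), E=(+1,0), S=(0,-1), W=(-1,0).

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

static const int DX[4] = {0, 1, 0, -1};
static const int DY[4] = {1, 0, -1, 0};

// condition codes
enum Cond { VISUAL_HAPTIC = 0, HAPTIC = 1, NAVIGATION = 2 };
// agent codes
enum Agent { AG_MB = 0, AG_MF = 1, AG_HYBRID = 2, AG_RANDOM = 3 };

static inline int succ0(int s, int a, int W, int H) {
  // 0-based successor of 0-based state s under 0-based action a; -1 off-grid
  int x = s % W + DX[a];
  int y = s / W + DY[a];
  if (x < 0 || x >= W || y < 0 || y >= H) return -1;
  return x + y * W;
}

// Toward-observation update of the transition belief: every in-bounds pair
// (q, a) whose intended cell is `cell` moves toward h by fraction alpha.
static inline void observe_cell(std::vector<double>& T, int n, int cell,
                                double h, double alpha, int W, int H) {
  for (int d = 0; d < 4; ++d) {
    int q = succ0(cell, d, W, H); // neighbour on side d
    if (q < 0) continue;
    int a = (d + 2) % 4;          // action from q back into cell
    double& t = T[q + a * n];
    t += alpha * (h - t);
  }
}

// Synchronous Bellman sweeps V(s) <- max_a T(s,a)[R(s,a) + gamma V(s')],
// with the target treated as terminating (its outgoing pairs masked).
// Returns number of sweeps used, or -1 if max_iter exceeded. Residuals
// (sup-norm change per sweep) are appended to `resids` when not NULL.
static int bellman_solve(const std::vector<double>& T, int n, int W, int H,
                         int target, double gamma, double tol, int max_iter,
                         std::vector<double>& V, double* final_resid,
                         std::vector<double>* resids = nullptr) {
  std::vector<double> Vn(n);
  double resid = R_PosInf;
  for (int it = 1; it <= max_iter; ++it) {
    resid = 0.0;
    for (int s = 0; s < n; ++s) {
      if (s == target) { Vn[s] = 0.0; continue; }
      double best = 0.0;
      for (int a = 0; a < 4; ++a) {
        int sp = succ0(s, a, W, H);
        if (sp < 0) continue;
        double r = (sp == target) ? 1.0 : 0.0;
        double v = T[s + a * n] * (r + gamma * V[sp]);
        if (v > best) best = v;
      }
      Vn[s] = best;
      double d = std::fabs(Vn[s] - V[s]);
      if (d > resid) resid = d;
    }
    V = Vn;
    if (resids) resids->push_back(resid);
    if (resid < tol) { *final_resid = resid; return it; }
  }
  *final_resid = resid;
  return -1;
}

// [[Rcpp::export]]
List cpp_value_iteration(NumericMatrix T, int W, int H, int target,
                         double gamma, double tol, int max_iter,
                         NumericVector V0) {
  int n = W * H;
  std::vector<double> Tv(T.begin(), T.end());
  std::vector<double> V(V0.begin(), V0.end());
  std::vector<double> resids;
  double resid;
  int it = bellman_solve(Tv, n, W, H, target - 1, gamma, tol, max_iter, V,
                         &resid, &resids);
  return List::create(_["V"] = NumericVector(V.begin(), V.end()),
                      _["iterations"] = (it < 0 ? max_iter : it),
                      _["converged"] = (it > 0),
                      _["residual"] = resid,
                      _["residual_trace"] =
                          NumericVector(resids.begin(), resids.end()));
}

// Boltzmann probability of the chosen action over an action subset given
// per-action preferences m (only entries with mask true participate).
static inline double softmax_prob(const double* m, const bool* mask,
                                  int chosen, double tau) {
  double mx = -1e300;
  for (int a = 0; a < 4; ++a)
    if (mask[a] && m[a] > mx) mx = m[a];
  double den = 0.0, num = 0.0;
  for (int a = 0; a < 4; ++a) {
    if (!mask[a]) continue;
    double e = std::exp((m[a] - mx) / tau);
    den += e;
    if (a == chosen) num = e;
  }
  return num / den;
}

static inline void init_T(std::vector<double>& T, const int* blk, int n,
                          int W, int H, int condition, double p0) {
  std::fill(T.begin(), T.end(), 0.0);
  for (int s = 0; s < n; ++s)
    for (int a = 0; a < 4; ++a) {
      int sp = succ0(s, a, W, H);
      if (sp < 0) continue;
      T[s + a * n] = (condition == VISUAL_HAPTIC) ? (blk[sp] ? 0.0 : 1.0) : p0;
    }
}

static inline void look_around(std::vector<double>& T, const int* blk, int n,
                               int cell, double alpha, int W, int H) {
  // 3x3 neighbourhood centred on `cell`, in-bounds cells only
  int x0 = cell % W, y0 = cell / W;
  for (int dx = -1; dx <= 1; ++dx)
    for (int dy = -1; dy <= 1; ++dy) {
      int x = x0 + dx, y = y0 + dy;
      if (x < 0 || x >= W || y < 0 || y >= H) continue;
      int c = x + y * W;
      observe_cell(T, n, c, blk[c] ? 0.0 : 1.0, alpha, W, H);
    }
}

static inline void look_ahead(std::vector<double>& T, const int* blk, int n,
                              int cell, int heading, double alpha, int W,
                              int H) {
  // the row of three cells one step beyond `cell` in the heading direction
  int x0 = cell % W + DX[heading], y0 = cell / W + DY[heading];
  int px = DY[heading], py = DX[heading]; // perpendicular flank offset
  for (int k = -1; k <= 1; ++k) {
    int x = x0 + k * px, y = y0 + k * py;
    if (x < 0 || x >= W || y < 0 || y >= H) continue;
    int c = x + y * W;
    observe_cell(T, n, c, blk[c] ? 0.0 : 1.0, alpha, W, H);
  }
}

// Teacher-forced replay of the model-based learner over one participant's
// step records. Returns, per executed step, the probability assigned to
// the observed action, renormalized over the given action set
// (reach_only = true: actions into open cells; false: all in-bounds).
// [[Rcpp::export]]
NumericVector cpp_replay_mb(int W, int H, IntegerMatrix blocked,
                            IntegerVector target, IntegerVector step_maze,
                            IntegerVector step_state,
                            IntegerVector step_action,
                            LogicalVector new_trial, LogicalVector new_maze,
                            IntegerVector contact_action,
                            IntegerVector contact_ptr, int condition,
                            double alpha, double gamma, double p0, double tau,
                            double tol, int max_iter, bool reach_only) {
  int n = W * H, nt = step_state.size();
  NumericVector out(nt);
  std::vector<double> T(n * 4), V(n);
  bool dirty = true;
  int tgt = -1;
  const int* blk = nullptr;
  double resid;

  for (int t = 0; t < nt; ++t) {
    int mz = step_maze[t] - 1;
    if (new_maze[t]) {
      blk = &blocked(0, mz);
      tgt = target[mz] - 1;
      init_T(T, blk, n, W, H, condition, p0);
      std::fill(V.begin(), V.end(), 0.0);
      dirty = true;
    }
    int s = step_state[t] - 1;
    if (condition == NAVIGATION && new_trial[t]) {
      look_around(T, blk, n, s, alpha, W, H);
      dirty = true;
    }
    if (dirty) {
      if (bellman_solve(T, n, W, H, tgt, gamma, tol, max_iter, V, &resid) < 0)
        stop("value iteration did not converge (residual %g)", resid);
      dirty = false;
    }
    // policy at s over the requested action set
    double m[4];
    bool mask[4];
    for (int a = 0; a < 4; ++a) {
      int sp = succ0(s, a, W, H);
      if (sp < 0) { mask[a] = false; m[a] = 0.0; continue; }
      mask[a] = reach_only ? !blk[sp] : true;
      double r = (sp == tgt) ? 1.0 : 0.0;
      m[a] = T[s + a * n] * (r + gamma * (sp == tgt ? 0.0 : V[sp]));
    }
    out[t] = softmax_prob(m, mask, step_action[t] - 1, tau);
    // belief updates from this step's events (learned-map conditions only)
    if (condition != VISUAL_HAPTIC) {
      for (int k = contact_ptr[t]; k < contact_ptr[t + 1]; ++k) {
        int sp = succ0(s, contact_action[k] - 1, W, H);
        if (sp >= 0) observe_cell(T, n, sp, 0.0, alpha, W, H);
      }
      int sp = succ0(s, step_action[t] - 1, W, H);
      observe_cell(T, n, sp, 1.0, alpha, W, H);
      if (condition == NAVIGATION)
        look_ahead(T, blk, n, sp, step_action[t] - 1, alpha, W, H);
      dirty = true;
    }
  }
  return out;
}

// Lazy-decay eligibility trace state for the Q(lambda) learner
struct Trace {
  std::vector<double> ehat; // e = ehat * g
  std::vector<int> active;
  std::vector<char> is_active;
  double g;
  Trace(int sz) : ehat(sz, 0.0), is_active(sz, 0), g(1.0) {}
  void clear() {
    for (int p : active) { ehat[p] = 0.0; is_active[p] = 0; }
    active.clear();
    g = 1.0;
  }
  void decay(double gl) {
    g *= gl;
    if (g < 1e-200) {
      for (int p : active) ehat[p] *= g;
      g = 1.0;
    }
  }
  void bump(int p) {
    if (!is_active[p]) { is_active[p] = 1; active.push_back(p); }
    ehat[p] += 1.0 / g;
  }
};

static inline double max_q(const std::vector<double>& Q, int n, int s, int W,
                           int H) {
  double mx = -1e300;
  for (int a = 0; a < 4; ++a) {
    if (succ0(s, a, W, H) < 0) continue;
    double q = Q[s + a * n];
    if (q > mx) mx = q;
  }
  return mx;
}

// Teacher-forced replay of the model-free Q(lambda) learner. Block-contact
// events never touch Q or the trace; only executed transitions count.
// [[Rcpp::export]]
NumericVector cpp_replay_mf(int W, int H, IntegerMatrix blocked,
                            IntegerVector target, IntegerVector step_maze,
                            IntegerVector step_state,
                            IntegerVector step_action,
                            LogicalVector new_trial, LogicalVector new_maze,
                            double alpha, double gamma, double lambda,
                            double tau, bool reset, bool reach_only) {
  int n = W * H, nt = step_state.size();
  NumericVector out(nt);
  std::vector<double> Q(n * 4, 0.0);
  Trace e(n * 4);
  int tgt = -1;
  const int* blk = nullptr;

  for (int t = 0; t < nt; ++t) {
    int mz = step_maze[t] - 1;
    if (new_maze[t]) {
      blk = &blocked(0, mz);
      tgt = target[mz] - 1;
      if (reset) std::fill(Q.begin(), Q.end(), 0.0);
    }
    if (new_trial[t]) e.clear();
    int s = step_state[t] - 1;
    double m[4];
    bool mask[4];
    for (int a = 0; a < 4; ++a) {
      int sp = succ0(s, a, W, H);
      if (sp < 0) { mask[a] = false; m[a] = 0.0; continue; }
      mask[a] = reach_only ? !blk[sp] : true;
      m[a] = Q[s + a * n];
    }
    int a = step_action[t] - 1;
    out[t] = softmax_prob(m, mask, a, tau);
    // decay-then-increment trace, then apply the scalar prediction error
    e.decay(gamma * lambda);
    e.bump(s + a * n);
    int sp = succ0(s, a, W, H);
    double r = (sp == tgt) ? 1.0 : 0.0;
    double delta = r + gamma * max_q(Q, n, sp, W, H) - Q[s + a * n];
    if (delta != 0.0)
      for (int p : e.active) Q[p] += alpha * (e.ehat[p] * e.g) * delta;
  }
  return out;
}

// Closed-loop autonomous simulation of an agent over a maze set.
// starts: n_trials x n_mazes matrix of 1-based start cells.
// w_trial: per-trial MF weight (ignored for MB/MF/RANDOM agents).
// Uses R's RNG stream, so results are reproducible under set.seed().
// [[Rcpp::export]]
List cpp_simulate(int W, int H, IntegerMatrix blocked, IntegerVector target,
                  IntegerMatrix starts, int condition, int agent,
                  double mb_alpha, double mb_gamma, double mb_p0,
                  double mb_tau, double mf_alpha, double mf_gamma,
                  double mf_lambda, double mf_tau, bool mf_reset,
                  NumericVector w_trial, int max_steps, double tol,
                  int max_iter) {
  int n = W * H;
  int n_mazes = blocked.ncol(), n_trials = starts.nrow();
  bool use_mb = (agent == AG_MB || agent == AG_HYBRID);
  bool use_mf = (agent == AG_MF || agent == AG_HYBRID);

  std::vector<double> T(n * 4), V(n), Q(n * 4, 0.0);
  Trace e(n * 4);
  double resid;

  // outputs
  std::vector<int> tr_maze, tr_trial, tr_steps;
  std::vector<int> su;
  std::vector<int> st_maze, st_trial, st_step, st_state, st_action;
  std::vector<int> ct_action, ct_ptr;
  ct_ptr.push_back(0);

  for (int mz = 0; mz < n_mazes; ++mz) {
    const int* blk = &blocked(0, mz);
    int tgt = target[mz] - 1;
    bool dirty = true;
    if (use_mb) {
      init_T(T, blk, n, W, H, condition, mb_p0);
      std::fill(V.begin(), V.end(), 0.0);
    }
    if (use_mf && mf_reset) std::fill(Q.begin(), Q.end(), 0.0);
    for (int trial = 0; trial < n_trials; ++trial) {
      e.clear();
      int s = starts(trial, mz) - 1;
      double w = (agent == AG_MB) ? 0.0
                 : (agent == AG_MF) ? 1.0
                                    : w_trial[trial];
      if (use_mb && condition == NAVIGATION) {
        look_around(T, blk, n, s, mb_alpha, W, H);
        dirty = true;
      }
      bool success = false;
      int step = 0;
      while (step < max_steps) {
        ++step;
        if (use_mb && dirty) {
          if (bellman_solve(T, n, W, H, tgt, mb_gamma, tol, max_iter, V,
                            &resid) < 0)
            stop("value iteration did not converge (residual %g)", resid);
          dirty = false;
        }
        // mixture distribution over in-bounds actions
        double pmb[4], pmf[4], p[4];
        bool mask[4];
        int n_opts = 0;
        for (int a = 0; a < 4; ++a) {
          mask[a] = succ0(s, a, W, H) >= 0;
          if (mask[a]) ++n_opts;
        }
        if (n_opts == 0) stop("state has no in-bounds actions");
        if (agent == AG_RANDOM) {
          for (int a = 0; a < 4; ++a) p[a] = mask[a] ? 1.0 / n_opts : 0.0;
        } else {
          double mmb[4], mmf[4];
          for (int a = 0; a < 4; ++a) {
            mmb[a] = 0.0;
            mmf[a] = 0.0;
            if (!mask[a]) continue;
            int sp = succ0(s, a, W, H);
            if (use_mb) {
              double r = (sp == tgt) ? 1.0 : 0.0;
              mmb[a] = T[s + a * n] * (r + mb_gamma * (sp == tgt ? 0.0 : V[sp]));
            }
            if (use_mf) mmf[a] = Q[s + a * n];
          }
          for (int a = 0; a < 4; ++a) {
            pmb[a] = use_mb ? 0.0 : (mask[a] ? 1.0 / n_opts : 0.0);
            pmf[a] = use_mf ? 0.0 : (mask[a] ? 1.0 / n_opts : 0.0);
          }
          if (use_mb) {
            double tot = 0.0, mx = -1e300;
            for (int a = 0; a < 4; ++a)
              if (mask[a] && mmb[a] > mx) mx = mmb[a];
            for (int a = 0; a < 4; ++a)
              if (mask[a]) tot += (pmb[a] = std::exp((mmb[a] - mx) / mb_tau));
            for (int a = 0; a < 4; ++a) pmb[a] /= tot;
          }
          if (use_mf) {
            double tot = 0.0, mx = -1e300;
            for (int a = 0; a < 4; ++a)
              if (mask[a] && mmf[a] > mx) mx = mmf[a];
            for (int a = 0; a < 4; ++a)
              if (mask[a]) tot += (pmf[a] = std::exp((mmf[a] - mx) / mf_tau));
            for (int a = 0; a < 4; ++a) pmf[a] /= tot;
          }
          for (int a = 0; a < 4; ++a)
            p[a] = mask[a] ? (1.0 - w) * pmb[a] + w * pmf[a] : 0.0;
        }
        // draw; on block contact remove the option and renormalize the
        // original mixture over the remaining options
        int a_exec = -1, n_contacts_here = 0;
        bool remaining[4];
        for (int a = 0; a < 4; ++a) remaining[a] = mask[a];
        while (true) {
          double tot = 0.0;
          for (int a = 0; a < 4; ++a)
            if (remaining[a]) tot += p[a];
          if (tot <= 0.0) stop("no remaining open action (walled-in state)");
          double u = unif_rand() * tot, cum = 0.0;
          int a_draw = -1;
          for (int a = 0; a < 4; ++a) {
            if (!remaining[a]) continue;
            cum += p[a];
            if (u <= cum) { a_draw = a; break; }
          }
          if (a_draw < 0) { // numerical edge: take last remaining
            for (int a = 3; a >= 0; --a)
              if (remaining[a]) { a_draw = a; break; }
          }
          int sp = succ0(s, a_draw, W, H);
          if (blk[sp]) {
            ct_action.push_back(a_draw + 1);
            ++n_contacts_here;
            if (use_mb && condition != VISUAL_HAPTIC) {
              observe_cell(T, n, sp, 0.0, mb_alpha, W, H);
              dirty = true;
            }
            remaining[a_draw] = false;
          } else {
            a_exec = a_draw;
            break;
          }
        }
        int sp = succ0(s, a_exec, W, H);
        // record
        st_maze.push_back(mz + 1);
        st_trial.push_back(trial + 1);
        st_step.push_back(step);
        st_state.push_back(s + 1);
        st_action.push_back(a_exec + 1);
        ct_ptr.push_back((int)ct_action.size());
        // learner updates on the executed transition
        if (use_mf) {
          e.decay(mf_gamma * mf_lambda);
          e.bump(s + a_exec * n);
          double r = (sp == tgt) ? 1.0 : 0.0;
          double delta = r + mf_gamma * max_q(Q, n, sp, W, H) - Q[s + a_exec * n];
          if (delta != 0.0)
            for (int pp : e.active) Q[pp] += mf_alpha * (e.ehat[pp] * e.g) * delta;
        }
        if (use_mb && condition != VISUAL_HAPTIC) {
          observe_cell(T, n, sp, 1.0, mb_alpha, W, H);
          dirty = true;
          if (condition == NAVIGATION)
            look_ahead(T, blk, n, sp, a_exec, mb_alpha, W, H);
        }
        s = sp;
        if (s == tgt) { success = true; break; }
      }
      tr_maze.push_back(mz + 1);
      tr_trial.push_back(trial + 1);
      tr_steps.push_back(step);
      su.push_back(success ? 1 : 0);
    }
  }
  return List::create(
      _["trial_maze"] = IntegerVector(tr_maze.begin(), tr_maze.end()),
      _["trial_index"] = IntegerVector(tr_trial.begin(), tr_trial.end()),
      _["trial_steps"] = IntegerVector(tr_steps.begin(), tr_steps.end()),
      _["trial_success"] = IntegerVector(su.begin(), su.end()),
      _["step_maze"] = IntegerVector(st_maze.begin(), st_maze.end()),
      _["step_trial"] = IntegerVector(st_trial.begin(), st_trial.end()),
      _["step_index"] = IntegerVector(st_step.begin(), st_step.end()),
      _["step_state"] = IntegerVector(st_state.begin(), st_state.end()),
      _["step_action"] = IntegerVector(st_action.begin(), st_action.end()),
      _["contact_action"] = IntegerVector(ct_action.begin(), ct_action.end()),
      _["contact_ptr"] = IntegerVector(ct_ptr.begin(), ct_ptr.end()));
}

// Monte-Carlo random-walk baseline for one (maze, start) pair: a uniform
// draw over in-bounds actions with the contact-resample rule and no
// learning. Returns per-repetition success flags and step counts.
// [[Rcpp::export]]
List cpp_random_baseline(int W, int H, IntegerVector blocked, int target,
                         int start, int max_steps, int n_reps) {
  int tgt = target - 1;
  IntegerVector success(n_reps), steps(n_reps);
  for (int rep = 0; rep < n_reps; ++rep) {
    int s = start - 1, step = 0;
    bool ok = (s == tgt);
    while (!ok && step < max_steps) {
      ++step;
      // executed action is uniform over actions into open in-bounds cells
      int open[4], n_open = 0;
      for (int a = 0; a < 4; ++a) {
        int sp = succ0(s, a, W, H);
        if (sp >= 0 && !blocked[sp]) open[n_open++] = a;
      }
      if (n_open == 0) stop("walled-in state in baseline walk");
      int a = open[(int)(unif_rand() * n_open) % n_open];
      s = succ0(s, a, W, H);
      if (s == tgt) ok = true;
    }
    success[rep] = ok ? 1 : 0;
    steps[rep] = (s == tgt && step == 0) ? 0 : step;
  }
  return List::create(_["success"] = success, _["steps"] = steps);
}
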