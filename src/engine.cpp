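// Tabular hierarchical model-based RL engine: world models with add-one
// smoothing, prioritized sweeping under per-step budgets, cross-level goal
// selection, successive A* plan refinement, model-free base (lesion variant)
// and a likelihood-based context bank. All randomness flows through R's RNG
// so set.seed() fully determines every trajectory.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <array>
#include <cmath>
#include <memory>
#include <limits>
#include <tuple>
#include <algorithm>

using namespace Rcpp;

static const int NA_ACT = 4; // actions 0..3 = up, down, left, right

// row delta / col delta per action
static const int DR[4] = {-1, 1, 0, 0};
static const int DC[4] = {0, 0, -1, 1};

// geometric successor on a rows x cols grid; -1 when the move leaves the grid
static inline int gsucc(int rows, int cols, int s, int a) {
  int r = s / cols + DR[a];
  int c = s % cols + DC[a];
  if (r < 0 || r >= rows || c < 0 || c >= cols) return -1;
  return r * cols + c;
}

static inline int manhattan(int cols, int s, int t) {
  return std::abs(s / cols - t / cols) + std::abs(s % cols - t % cols);
}

struct Maze {
  int rows = 0, cols = 0, start = 0, goal = 0, cap = 5000;
  double goal_reward = 100.0, wall_penalty = -1.0;
  std::vector<uint8_t> wall;
};

static Maze parseMaze(const List& m) {
  Maze z;
  z.rows = as<int>(m["rows"]);
  z.cols = as<int>(m["cols"]);
  z.start = as<int>(m["start0"]);  // 0-based cell index
  z.goal = as<int>(m["goal0"]);
  z.goal_reward = as<double>(m["goal_reward"]);
  z.wall_penalty = as<double>(m["wall_penalty"]);
  z.cap = as<int>(m["step_cap"]);
  IntegerVector w = m["wall0"];    // 0/1 per cell, row-major
  z.wall.assign(w.begin(), w.end());
  return z;
}

struct Level {
  int rows = 0, cols = 0, n = 0;
  double gamma = 0.9;
  int budget = 20;
  bool model_based = true;
  std::vector<int> T;        // n*4*2 counts: slot 0 geometric succ, slot 1 self
  std::vector<double> Rm;    // running-mean reward per (s,a,slot)
  std::vector<double> Q;     // n*4
  std::vector<uint8_t> terminal;
  // prioritized-sweeping queue with lazy invalidation
  std::vector<double> pri;
  std::priority_queue<std::pair<double, int>> pq;
  // reward-distribution variant (context likelihoods); up to 8 distinct values
  bool rdist = false;
  std::vector<std::array<int, 8>> rcnt;
  // macro bookkeeping: a macro transition (prev -> cur) is recorded when the
  // agent leaves cur (or the trial ends), carrying the maximum reward
  // experienced during the occupancy of cur
  double accum = 0.0;
  int cur_macro = 0;
  int prev_macro = -1;   // -1: no pending crossing this episode
  int entry_act = 0;     // action that carried the pending crossing
  // cached goal-selection argmax
  bool max_dirty = true;
  double best_q = 0.0;
  int best_s = -1, best_a = -1;
  // A* scratch (stamped so no per-call clearing)
  std::vector<int> stamp_g, from;
  std::vector<double> gval;
  std::vector<int> stamp_allow, stamp_closed;
  int stamp = 0;

  inline int idx(int s, int a, int slot) const { return (s * 4 + a) * 2 + slot; }
  inline double maxQ(int s) const {
    const double* q = &Q[s * 4];
    double m = q[0];
    if (q[1] > m) m = q[1];
    if (q[2] > m) m = q[2];
    if (q[3] > m) m = q[3];
    return m;
  }
};

struct Cfg {
  double epsilon = 0.8;
  double optimism = 1.0;
  double pri_threshold = 1e-4;
  double alpha = 0.1;        // model-free learning rate (dorsal-lesion agent)
  bool rdist = false;        // enable reward-distribution tables at level 0
  double goal_tol = 0.1;     // relative tolerance for cross-level goal ties
  int plan_budget = 120;     // forward-sweep expansions per planning call
                             // (the agent's total per-step budget)
};

class NavAgent {
public:
  Maze maze;
  Cfg cfg;
  std::vector<Level> levels;
  std::vector<std::vector<int>> absmap;            // level -> base cell -> macro id
  std::vector<std::vector<int>> upmap;             // level>=1 -> state below -> macro
  std::vector<std::vector<std::vector<int>>> kids; // level>=1 -> macro -> child states one level down
  long long accesses = 0;
  // whether any positive reward has entered the base model (a context with
  // none is still "unidentified" and claims the first reward it finds)
  bool has_reward = false;
  // diagnostics: level whose plan produced the last planned action
  // (-1 cached-greedy fallback, -9 none yet)
  int last_plan_level = -9;
  // reward-value registry for the distribution variant
  std::vector<double> rvals;

  NavAgent(const List& mazeL, const List& levelsL, const List& cfgL) {
    maze = parseMaze(mazeL);
    cfg.epsilon = as<double>(cfgL["epsilon"]);
    cfg.optimism = as<double>(cfgL["optimism"]);
    cfg.pri_threshold = as<double>(cfgL["priority_threshold"]);
    cfg.alpha = as<double>(cfgL["alpha"]);
    cfg.rdist = as<bool>(cfgL["reward_dist"]);
    cfg.goal_tol = as<double>(cfgL["goal_tie_tol"]);

    int nlev = levelsL.size();
    levels.resize(nlev);
    absmap.resize(nlev);
    upmap.resize(nlev);
    kids.resize(nlev);
    for (int k = 0; k < nlev; ++k) {
      List lv = levelsL[k];
      Level& L = levels[k];
      L.rows = as<int>(lv["rows"]);
      L.cols = as<int>(lv["cols"]);
      L.n = L.rows * L.cols;
      L.gamma = as<double>(lv["gamma"]);
      L.budget = as<int>(lv["budget"]);
      if (k == 0) cfg.plan_budget = 0;
      cfg.plan_budget += L.budget;
      L.model_based = as<bool>(lv["model_based"]);
      L.T.assign((size_t)L.n * 8, 0);
      L.Rm.assign((size_t)L.n * 8, 0.0);
      double q0 = L.model_based ? cfg.optimism : 0.0;
      L.Q.assign((size_t)L.n * 4, q0);
      L.terminal.assign(L.n, 0);
      L.pri.assign(L.n, 0.0);
      L.stamp_g.assign(L.n, 0);
      L.gval.assign(L.n, 0.0);
      L.from.assign(L.n, -1);
      L.stamp_allow.assign(L.n, 0);
      L.stamp_closed.assign(L.n, 0);
      if (k == 0 && cfg.rdist) {
        L.rdist = true;
        L.rcnt.assign((size_t)L.n * 8, std::array<int, 8>{});
      }
      if (k == 0) {
        absmap[0].resize(L.n);
        for (int s = 0; s < L.n; ++s) absmap[0][s] = s;
      } else {
        IntegerVector up = lv["up"]; // level k-1 state -> level k state, 0-based
        upmap[k].assign(up.begin(), up.end());
        const std::vector<int>& below = absmap[k - 1];
        absmap[k].resize(levels[0].n);
        for (int s = 0; s < levels[0].n; ++s) absmap[k][s] = up[below[s]];
        kids[k].resize(L.n);
        for (int x = 0; x < levels[k - 1].n; ++x) kids[k][up[x]].push_back(x);
      }
      L.cur_macro = absmap[k][maze.start];
    }
  }

  int nLevels() const { return (int)levels.size(); }
  void setGoal(int cell0) { maze.goal = cell0; }
  void setWalls(IntegerVector w) {
    if ((int)w.size() != levels[0].n) stop("wall vector has wrong length");
    maze.wall.assign(w.begin(), w.end());
  }
  long long accessCount() const { return accesses; }

  // ---------------- world model ----------------

  int rslot(double r, bool create) {
    for (size_t i = 0; i < rvals.size(); ++i)
      if (rvals[i] == r) return (int)i;
    if (!create) return -1;
    if (rvals.size() >= 8) stop("too many distinct reward values");
    rvals.push_back(r);
    return (int)rvals.size() - 1;
  }

  // slot of sp within the candidate set of (s,a); -1 if not a candidate
  inline int slotOf(const Level& L, int s, int a, int sp) const {
    int g = gsucc(L.rows, L.cols, s, a);
    if (sp == s) return 1;
    if (g >= 0 && sp == g) return 0;
    return -1;
  }

  // negative self-evidence at macro levels (physical or imagined bumps)
  // saturates shortly past the majority flip, so a wrongly blocked macro
  // edge can be reopened by a few contrary crossings
  void macroBump(int lev, int s, int a, double r) {
    modelObserve(lev, s, a, s, r, false);
  }

  void modelObserve(int lev, int s, int a, int sp, double r, bool term) {
    Level& L = levels[lev];
    int slot = slotOf(L, s, a, sp);
    if (slot < 0) return; // not an admissible successor; ignore defensively
    int i = L.idx(s, a, slot);
    L.T[i] += 1;
    L.Rm[i] += (r - L.Rm[i]) / L.T[i];
    accesses += 2;
    if (lev == 0 && r > 0) has_reward = true;
    if (L.rdist) {
      L.rcnt[i][rslot(r, true)] += 1;
      accesses += 1;
    }
    if (term && !L.terminal[sp]) {
      // absorbing state: zero continuation value by definition; drop any
      // queued update
      L.terminal[sp] = 1;
      for (int b = 0; b < 4; ++b) setQ(L, sp, b, 0.0);
      L.pri[sp] = 0.0;
    }
    // seed the sweep queue with the experienced state ...
    double p = std::fabs(backup(lev, s, a) - L.Q[s * 4 + a]);
    if (p > cfg.pri_threshold) push(L, s, p);
    // ... and with the state just entered, so newly visited states are
    // re-valued promptly (their optimistic initial values decay on the
    // first sweep after first entry)
    if (sp != s) {
      double psp = 0.0;
      for (int b = 0; b < 4; ++b)
        psp = std::max(psp, std::fabs(backup(lev, sp, b) - L.Q[sp * 4 + b]));
      if (psp > cfg.pri_threshold) push(L, sp, psp);
    }
  }

  double transitionProb(int lev, int s, int a, int sp) {
    const Level& L = levels[lev];
    int g = gsucc(L.rows, L.cols, s, a);
    double denom = 0.0;
    if (g >= 0 && g != s) denom += L.T[L.idx(s, a, 0)] + 1.0;
    denom += L.T[L.idx(s, a, 1)] + 1.0;
    int slot = slotOf(L, s, a, sp);
    if (slot < 0) return 0.0;
    return (L.T[L.idx(s, a, slot)] + 1.0) / denom;
  }

  // P(r | s, a, sp) with add-one smoothing over reward values seen anywhere
  double rewardProb(int s, int a, int sp, double r) {
    const Level& L = levels[0];
    if (!L.rdist) return 1.0; // no distribution tracked: uninformative factor
    int slot = slotOf(L, s, a, sp);
    if (slot < 0) return 0.0;
    int i = L.idx(s, a, slot);
    int seen = rslot(r, false);
    int nv = (int)rvals.size() + (seen < 0 ? 1 : 0);
    int cnt = (seen < 0) ? 0 : L.rcnt[i][seen];
    int tot = L.T[i];
    return (cnt + 1.0) / (tot + nv);
  }

  double experienceProb(int s, int a, int sp, double r) {
    accesses += 2;
    double pt = transitionProb(0, s, a, sp);
    if (pt <= 0.0) return 0.0;
    return pt * rewardProb(s, a, sp, r);
  }

  // aggregated count of occurrences of reward r on entries into sp
  long long rewardCountAt(int sp, double r) {
    const Level& L = levels[0];
    if (!L.rdist) return 0;
    int seen = rslot(r, false);
    if (seen < 0) return 0;
    long long c = 0;
    for (int a = 0; a < 4; ++a) {
      int p = gsucc(L.rows, L.cols, sp, (a % 2 == 0) ? a + 1 : a - 1);
      if (p >= 0 && p != sp && gsucc(L.rows, L.cols, p, a) == sp)
        c += L.rcnt[L.idx(p, a, 0)][seen];
      c += L.rcnt[L.idx(sp, a, 1)][seen];
    }
    return c;
  }

  // does the base model hold a positive mean reward on any entry into sp?
  bool believesRewardAt(int sp) {
    const Level& L = levels[0];
    for (int a = 0; a < 4; ++a) {
      int p = gsucc(L.rows, L.cols, sp, (a % 2 == 0) ? a + 1 : a - 1);
      if (p >= 0 && p != sp && gsucc(L.rows, L.cols, p, a) == sp) {
        int i = L.idx(p, a, 0);
        if (L.T[i] > 0 && L.Rm[i] > 0) return true;
      }
      int i = L.idx(sp, a, 1);
      if (L.T[i] > 0 && L.Rm[i] > 0) return true;
    }
    return false;
  }

  // P(r | arriving in sp), aggregated over every recorded entry into sp
  // (all geometric predecessors plus self-transitions); used to ask whether
  // a model expects this reward at this *place* regardless of approach
  double rewardProbState(int sp, double r) {
    const Level& L = levels[0];
    if (!L.rdist) return 0.0;
    long long tot = 0;
    std::array<long long, 8> cnt{};
    for (int a = 0; a < 4; ++a) {
      int p = gsucc(L.rows, L.cols, sp, (a % 2 == 0) ? a + 1 : a - 1);
      if (p >= 0 && p != sp && gsucc(L.rows, L.cols, p, a) == sp) {
        int i = L.idx(p, a, 0);
        tot += L.T[i];
        for (int j = 0; j < 8; ++j) cnt[j] += L.rcnt[i][j];
      }
      int i = L.idx(sp, a, 1);
      tot += L.T[i];
      for (int j = 0; j < 8; ++j) cnt[j] += L.rcnt[i][j];
    }
    // a place never entered carries no evidence: it cannot explain an
    // observed reward (the smoothed prior alone can reach the switching
    // threshold by sheer ignorance)
    if (tot == 0) return 0.0;
    int seen = rslot(r, false);
    int nv = (int)rvals.size() + (seen < 0 ? 1 : 0);
    if (nv == 0) nv = 1;
    long long c = (seen < 0) ? 0 : cnt[seen];
    accesses += 2;
    return (c + 1.0) / (tot + nv);
  }

  double historyLogProb(const std::vector<int>& s, const std::vector<int>& a,
                        const std::vector<int>& sp, const std::vector<double>& r) {
    double lp = 0.0;
    for (size_t i = 0; i < s.size(); ++i) {
      double p = experienceProb(s[i], a[i], sp[i], r[i]);
      lp += std::log(std::max(p, 1e-300));
    }
    return lp;
  }

  int predictedSuccessor(int lev, int s, int a) {
    const Level& L = levels[lev];
    int g = gsucc(L.rows, L.cols, s, a);
    int t0 = (g >= 0 && g != s) ? L.T[L.idx(s, a, 0)] : -1;
    int t1 = L.T[L.idx(s, a, 1)];
    if (t0 < 0) return s;                 // only the self candidate exists
    if (t0 == 0 && t1 == 0) return g;     // untried: geometric fallback
    if (t0 > t1) return g;
    if (t1 > t0) return s;
    return std::min(g, s);                // tie: lower state index
  }

  // ---------------- value computation ----------------

  double backup(int lev, int s, int a) {
    const Level& L = levels[lev];
    int g = gsucc(L.rows, L.cols, s, a);
    double v = 0.0, denom = 0.0;
    if (g >= 0 && g != s) denom += L.T[L.idx(s, a, 0)] + 1.0;
    denom += L.T[L.idx(s, a, 1)] + 1.0;
    if (g >= 0 && g != s) {
      int i = L.idx(s, a, 0);
      double cont = L.terminal[g] ? 0.0 : L.maxQ(g);
      v += (L.T[i] + 1.0) / denom * (L.Rm[i] + L.gamma * cont);
      accesses += 3;
    }
    int i = L.idx(s, a, 1);
    double cont = L.terminal[s] ? 0.0 : L.maxQ(s);
    v += (L.T[i] + 1.0) / denom * (L.Rm[i] + L.gamma * cont);
    accesses += 3;
    return v;
  }

  void push(Level& L, int s, double p) {
    if (L.terminal[s]) return;
    if (p > L.pri[s]) {
      L.pri[s] = p;
      L.pq.push({p, s});
    }
  }

  void setQ(Level& L, int s, int a, double v) {
    L.Q[s * 4 + a] = v;
    L.max_dirty = true;
    accesses += 1;
  }

  // pop up to `budget` states; returns number of state updates performed
  int sweep(int lev, int budget) {
    Level& L = levels[lev];
    if (!L.model_based) return 0;
    int done = 0;
    while (done < budget && !L.pq.empty()) {
      std::pair<double, int> top = L.pq.top();
      L.pq.pop();
      int s = top.second;
      if (top.first != L.pri[s]) continue; // stale entry
      L.pri[s] = 0.0;
      double oldmax = L.maxQ(s);
      for (int a = 0; a < 4; ++a) setQ(L, s, a, backup(lev, s, a));
      double d = std::fabs(L.maxQ(s) - oldmax);
      ++done;
      if (d > cfg.pri_threshold) {
        for (int a = 0; a < 4; ++a) {
          // predecessor whose action a leads geometrically into s
          int p = gsucc(L.rows, L.cols, s, (a % 2 == 0) ? a + 1 : a - 1);
          if (p < 0 || p == s) continue;
          if (L.T[L.idx(p, a, 0)] > 0) {
            double pr = d * transitionProb(lev, p, a, s);
            if (pr > cfg.pri_threshold) push(L, p, pr);
          }
        }
      }
      // every state is its own predecessor through the self candidate of
      // its backups: re-queue by the residual so self-referential values
      // iterate to their fixed point
      double res = 0.0;
      for (int a = 0; a < 4; ++a)
        res = std::max(res, std::fabs(backup(lev, s, a) - L.Q[s * 4 + a]));
      if (res > cfg.pri_threshold) push(L, s, res);
    }
    return done;
  }

  int queueSize(int lev) {
    Level& L = levels[lev];
    // count live entries only
    int live = 0;
    for (int s = 0; s < L.n; ++s)
      if (L.pri[s] > 0) ++live;
    return live;
  }

  void tdUpdate(int s, int a, int sp, double r, bool term) {
    Level& L = levels[0];
    double cont = term ? 0.0 : L.maxQ(sp);
    L.Q[s * 4 + a] += cfg.alpha * (r + L.gamma * cont - L.Q[s * 4 + a]);
    accesses += 3;
  }

  // ---------------- goal selection ----------------

  void rescan(int lev) {
    Level& L = levels[lev];
    L.best_q = -std::numeric_limits<double>::infinity();
    L.best_s = -1;
    L.best_a = -1;
    for (int s = 0; s < L.n; ++s) {
      if (L.terminal[s]) continue;
      for (int a = 0; a < 4; ++a) {
        double q = L.Q[s * 4 + a];
        if (q > L.best_q) {
          L.best_q = q;
          L.best_s = s;
          L.best_a = a;
        }
      }
    }
    L.max_dirty = false;
  }

  // goal implied by a level's best entry: its predicted successor, or the
  // source state itself when the entry is untried (no prediction exists yet;
  // the informative exploratory target is the source)
  int goalOf(int lev, int s, int a) {
    const Level& L = levels[lev];
    if (L.T[L.idx(s, a, 0)] == 0 && L.T[L.idx(s, a, 1)] == 0) return s;
    return predictedSuccessor(lev, s, a);
  }

  // candidate goal levels in preference order: cross-level comparison is on
  // raw Q magnitudes; "ties" prefer the higher level, operationalised as the
  // highest level whose maximum lies within a relative tolerance of the
  // global maximum (per-level discount tuning keeps the maxima comparable,
  // so exact float equality would never fire). Levels whose preferred goal
  // cannot be refined into a base action are skipped by the caller, which
  // then tries the remaining candidates in descending-value order.
  // Single-state levels carry no directional information and are excluded.
  std::vector<int> goalCandidates() {
    int nl = nLevels();
    std::vector<int> cand;
    double gmax = 0.0;
    for (int k = 0; k < nl; ++k) {
      Level& L = levels[k];
      if (!L.model_based || L.n <= 1) continue;
      if (L.max_dirty) rescan(k);
      accesses += 1;
      if (L.best_s >= 0 && L.best_q > gmax) gmax = L.best_q;
    }
    if (gmax <= 0) return cand;
    int pref = -1;
    for (int k = nl - 1; k >= 0; --k) {
      Level& L = levels[k];
      if (!L.model_based || L.n <= 1 || L.best_s < 0 || L.best_q <= 0) continue;
      if (pref < 0 && L.best_q >= gmax * (1.0 - cfg.goal_tol)) pref = k;
    }
    if (pref >= 0) cand.push_back(pref);
    // remaining levels by descending maximum value
    std::vector<std::pair<double, int>> rest;
    for (int k = 0; k < nl; ++k) {
      Level& L = levels[k];
      if (k == pref || !L.model_based || L.n <= 1 || L.best_s < 0 ||
          L.best_q <= 0)
        continue;
      rest.push_back({-L.best_q, k});
    }
    std::sort(rest.begin(), rest.end());
    for (auto& p : rest) cand.push_back(p.second);
    return cand;
  }

  List selectGoal() {
    std::vector<int> cand = goalCandidates();
    if (cand.empty()) return List::create(_["found"] = false);
    int bl = cand[0];
    int bs = levels[bl].best_s, ba = levels[bl].best_a;
    return List::create(_["found"] = true, _["level"] = bl, _["source"] = bs,
                        _["action"] = ba, _["goal"] = goalOf(bl, bs, ba));
  }

  // ---------------- A* planning ----------------

  // A* on a level's transition graph. Each geometric edge is weighted by the
  // expected number of attempts needed to cross it under the smoothed model,
  // 1 / P(cross) = (T_cross + T_self + 2) / (T_cross + 1): untried moves
  // cost ~2, well-travelled ones ~1, and moves observed to bounce back grow
  // expensive in proportion to the evidence — so new boundaries price old
  // routes out gradually, and a wrongly expensive edge remains finitely
  // priced and self-corrects when probed. The Manhattan heuristic stays
  // admissible because every edge costs more than 1. `allow` may restrict
  // the search region. `max_expand` bounds the number of node expansions
  // (the per-step forward-sweep budget of the level); exceeding it fails
  // the plan. Returns the state sequence (possibly just {src}), or empty on
  // failure.
  std::vector<int> astar(int lev, int src, const std::vector<int>& targets,
                         const std::vector<int>* allow,
                         int max_expand = std::numeric_limits<int>::max()) {
    Level& L = levels[lev];
    std::vector<int> out;
    if (targets.empty()) return out;
    L.stamp += 1;
    int st = L.stamp;
    if (allow) {
      for (int x : *allow) L.stamp_allow[x] = st;
      bool src_ok = false;
      for (int x : *allow) if (x == src) { src_ok = true; break; }
      if (!src_ok) L.stamp_allow[src] = st;
    }
    for (int t : targets)
      if (t == src) { out.push_back(src); return out; }

    // heuristic: Manhattan distance at the prior edge cost (an untried move
    // costs 2 expected attempts); exact on unexplored terrain, mildly
    // greedy where edges are already cheaper than the prior — keeping the
    // forward sweep focused within its expansion budget
    auto h = [&](int s) {
      int m = std::numeric_limits<int>::max();
      for (int t : targets) m = std::min(m, manhattan(L.cols, s, t));
      return 2.0 * m;
    };
    typedef std::tuple<double, double, int> Node; // f, tie(-Q), state
    std::priority_queue<Node, std::vector<Node>, std::greater<Node>> open;
    L.stamp_g[src] = st;
    L.gval[src] = 0.0;
    L.from[src] = -1;
    open.push(Node((double)h(src), 0.0, src));
    int expanded = 0;
    while (!open.empty()) {
      Node nd = open.top();
      open.pop();
      int s = std::get<2>(nd);
      if (L.stamp_closed[s] == st) continue;
      L.stamp_closed[s] = st;
      if (++expanded > max_expand) { out.clear(); return out; }
      for (int t : targets) {
        if (s == t) { // reconstruct
          for (int x = s; x >= 0; x = (x == src ? -1 : L.from[x])) out.push_back(x);
          std::reverse(out.begin(), out.end());
          return out;
        }
      }
      for (int a = 0; a < 4; ++a) {
        int c = gsucc(L.rows, L.cols, s, a);
        accesses += 3;
        if (c < 0 || c == s) continue;
        if (allow && L.stamp_allow[c] != st) continue;
        if (L.stamp_closed[c] == st) continue;
        int t0 = L.T[L.idx(s, a, 0)], t1 = L.T[L.idx(s, a, 1)];
        // overwhelming one-sided bounce evidence marks a certain wall;
        // anything ever crossed keeps a finite expected-attempts cost
        if (t0 == 0 && t1 >= 10) continue;
        double ng = L.gval[s] + (t0 + t1 + 2.0) / (t0 + 1.0);
        if (L.stamp_g[c] != st || ng < L.gval[c]) {
          L.stamp_g[c] = st;
          L.gval[c] = ng;
          L.from[c] = s;
          open.push(Node(ng + h(c), -L.Q[s * 4 + a], c));
        }
      }
    }
    return out; // empty: no path
  }

  IntegerVector planRoute(int lev, int src, IntegerVector targets) {
    std::vector<int> tg(targets.begin(), targets.end());
    std::vector<int> p = astar(lev, src, tg, nullptr);
    return IntegerVector(p.begin(), p.end());
  }

  // ---------------- action selection ----------------

  static inline int dirFromTo(int cols, int a, int b) {
    int dr = b / cols - a / cols, dc = b % cols - a % cols;
    if (dr == -1 && dc == 0) return 0;
    if (dr == 1 && dc == 0) return 1;
    if (dr == 0 && dc == -1) return 2;
    if (dr == 0 && dc == 1) return 3;
    return -1;
  }

  // refine a goal set at `gl` into a base action via successive A* sweeps,
  // or -1 when any level's plan fails. When the goal was lifted from a finer
  // level, `focus` names the original goal's ancestor one level below `gl`,
  // so the first refinement aims at the goal's own subregion rather than
  // anywhere inside the coarse macro-state.
  int planWithGoal(int s, int gl, int goal, int focus = -1) {
    if (gl == 0) {
      std::vector<int> tg(1, goal);
      std::vector<int> p = astar(0, s, tg, nullptr, cfg.plan_budget);
      if (p.size() < 2) return -1;
      return dirFromTo(levels[0].cols, p[0], p[1]);
    }
    int wp_above = goal;
    for (int lev = gl - 1; lev >= 0; --lev) {
      int cur = absmap[lev][s];
      std::vector<int> focus_tg;
      if (lev == gl - 1 && focus >= 0) focus_tg.push_back(focus);
      const std::vector<int>& tg =
          focus_tg.empty() ? kids[lev + 1][wp_above] : focus_tg;
      std::vector<int> p;
      if (lev == gl - 1) {
        p = astar(lev, cur, tg, nullptr, cfg.plan_budget);
        if (p.empty()) return -1;
      } else {
        std::vector<int> allow = kids[lev + 1][absmap[lev + 1][s]];
        allow.insert(allow.end(), tg.begin(), tg.end());
        p = astar(lev, cur, tg, &allow, cfg.plan_budget);
        if (p.empty()) {
          // the window search is exhaustive over the two macro-states, so
          // failure means the level-above step cannot currently be realised:
          // record it as negative (imagined) evidence against that macro
          // edge, the mental analogue of bumping into the boundary
          int ca = absmap[lev + 1][s];
          if (ca != wp_above) {
            int dir = dirFromTo(levels[lev + 1].cols, ca, wp_above);
            if (dir >= 0) macroBump(lev + 1, ca, dir, maze.wall_penalty);
          }
          return -1;
        }
      }
      int wp = (p.size() > 1) ? p[1] : p[0];
      if (lev == 0) {
        if (p.size() < 2) return -1;
        return dirFromTo(levels[0].cols, p[0], p[1]);
      }
      wp_above = wp;
    }
    return -1;
  }

  // plan through the hierarchy; returns base action or -1. Candidate goal
  // levels are tried in preference order; a goal whose refinement fails
  // (e.g. too distant for the per-level forward-sweep budget) is lifted to
  // the macro-state containing it one level up and re-planned at that
  // coarser resolution, zooming out until a plan fits the budget.
  int plannedAction(int s) {
    if (!levels[0].model_based) return dhPlanned(s);
    std::vector<int> cand = goalCandidates();
    for (int gl : cand) {
      int lev = gl;
      int gg = goalOf(gl, levels[gl].best_s, levels[gl].best_a);
      int focus = -1;
      while (true) {
        int a = planWithGoal(s, lev, gg, focus);
        if (a >= 0) {
          last_plan_level = lev;
          return a;
        }
        if (lev + 1 >= nLevels() || levels[lev + 1].n <= 1) break;
        focus = gg;
        gg = upmap[lev + 1][gg];
        ++lev;
      }
    }
    last_plan_level = -1;
    return -1;
  }

  int lastPlanLevel() const { return last_plan_level; }

  // dorsal-lesion composite policy: model-free base values plus the surviving
  // top-level macro values, greedy with uniform random tie-break
  int dhPlanned(int s) {
    const Level& L0 = levels[0];
    const Level& Lt = levels[nLevels() - 1];
    int m = absmap[nLevels() - 1][s];
    double best = -std::numeric_limits<double>::infinity();
    int nbest = 0;
    int cand[4];
    for (int a = 0; a < 4; ++a) {
      double v = L0.Q[s * 4 + a] + Lt.Q[m * 4 + a];
      accesses += 2;
      if (v > best + 1e-12) {
        best = v;
        nbest = 0;
        cand[nbest++] = a;
      } else if (std::fabs(v - best) <= 1e-12) {
        cand[nbest++] = a;
      }
    }
    if (nbest == 1) return cand[0];
    int k = (int)std::floor(unif_rand() * nbest);
    if (k >= nbest) k = nbest - 1;
    return cand[k];
  }

  // when no level's forward sweep produced a plan the agent acts uniformly
  // at random: an ergodic fallback that guarantees escape from regions the
  // model wrongly believes to be dead ends (re-crossing a blocked-in-belief
  // edge restores its evidence)
  int actInternal(int s, int& planned) {
    planned = plannedAction(s);
    if (planned >= 0) {
      if (unif_rand() < cfg.epsilon) return planned;
    }
    int a = (int)std::floor(unif_rand() * 4);
    if (a > 3) a = 3;
    return a;
  }

  IntegerVector act(int s) {
    RNGScope scope;
    int planned = -1;
    int ex = actInternal(s, planned);
    return IntegerVector::create(planned, ex);
  }

  // ---------------- environment ----------------

  List envStep(int s, int a) {
    int t = gsucc(levels[0].rows, levels[0].cols, s, a);
    int sp;
    double r;
    bool term = false;
    if (t < 0 || maze.wall[t]) {
      sp = s;
      r = maze.wall_penalty;
    } else if (t == maze.goal) {
      sp = t;
      r = maze.goal_reward;
      term = true;
    } else {
      sp = t;
      r = 0.0;
    }
    return List::create(_["sp"] = sp, _["r"] = r, _["term"] = term);
  }

  // ---------------- learning step across the hierarchy ----------------

  void onStep(int s, int a, int sp, double r, bool term) {
    bool bump = (sp == s) && !term;
    for (int k = 0; k < nLevels(); ++k) {
      Level& L = levels[k];
      if (k == 0) {
        if (L.model_based) modelObserve(0, s, a, sp, r, term);
        else tdUpdate(s, a, sp, r, term);
        continue;
      }
      if (bump) {
        // a blocked base move is negative evidence for crossing the macro
        // boundary in that direction; without it new walls would never
        // invalidate previously learned macro routes. The evidence exists
        // to repair hierarchical plans, so agents without a planning base
        // (the dorsal-lesion variant) do not collect it — at macro
        // granularity it would only repel them from boundary regions.
        if (levels[0].model_based) macroBump(k, L.cur_macro, a, r);
        L.accum = std::max(L.accum, r);
        continue;
      }
      int msp = absmap[k][sp];
      if (msp != L.cur_macro) {
        // leaving cur_macro completes its occupancy: record the pending
        // crossing into it with the max reward experienced there
        if (L.prev_macro >= 0)
          modelObserve(k, L.prev_macro, L.entry_act, L.cur_macro, L.accum,
                       false);
        int dir = dirFromTo(L.cols, L.cur_macro, msp);
        if (term) {
          // the trial ends on arrival: the destination occupancy is just
          // the goal reward
          if (dir >= 0) modelObserve(k, L.cur_macro, dir, msp, r, true);
        } else if (dir >= 0) {
          L.prev_macro = L.cur_macro;
          L.entry_act = dir;
          L.cur_macro = msp;
          L.accum = r;
        }
      } else {
        L.accum = std::max(L.accum, r);
        if (term && L.prev_macro >= 0)
          modelObserve(k, L.prev_macro, L.entry_act, L.cur_macro, L.accum,
                       true);
      }
    }
    for (int k = 0; k < nLevels(); ++k)
      if (levels[k].model_based) sweep(k, levels[k].budget);
  }

  void resetEpisode() {
    for (int k = 0; k < nLevels(); ++k) {
      levels[k].cur_macro = absmap[k][maze.start];
      levels[k].accum = 0.0;
      levels[k].prev_macro = -1;
    }
  }

  // run trials inside C++; goals may override the maze goal per trial
  List runTrials(int ntrials, int cap, IntegerVector goals) {
    RNGScope scope;
    IntegerVector steps(ntrials);
    NumericVector acc(ntrials);
    LogicalVector reached(ntrials);
    for (int tr = 0; tr < ntrials; ++tr) {
      if (goals.size() > 0) maze.goal = goals[tr % goals.size()];
      int s = maze.start;
      resetEpisode();
      int n = 0;
      bool ok = false;
      while (n < cap) {
        int planned;
        int a = actInternal(s, planned);
        List e = envStep(s, a);
        int sp = as<int>(e["sp"]);
        double r = as<double>(e["r"]);
        bool term = as<bool>(e["term"]);
        onStep(s, a, sp, r, term);
        ++n;
        if (term) { ok = true; break; }
        s = sp;
      }
      steps[tr] = n;
      acc[tr] = (double)accesses;
      reached[tr] = ok;
    }
    return List::create(_["steps"] = steps, _["accesses"] = acc,
                        _["reached"] = reached);
  }

  // ---------------- introspection / serialization ----------------

  NumericMatrix qValues(int lev) {
    const Level& L = levels[lev];
    NumericMatrix out(L.n, 4);
    for (int s = 0; s < L.n; ++s)
      for (int a = 0; a < 4; ++a) out(s, a) = L.Q[s * 4 + a];
    return out;
  }

  void setQValue(int lev, int s, int a, double v) { setQ(levels[lev], s, a, v); }

  IntegerVector levelDims(int lev) {
    return IntegerVector::create(levels[lev].rows, levels[lev].cols);
  }

  IntegerVector parentMap(int lev) {
    return IntegerVector(absmap[lev].begin(), absmap[lev].end());
  }

  DataFrame exportModel(int lev) {
    const Level& L = levels[lev];
    std::vector<int> vs, va, vsp, vn, vterm;
    std::vector<double> vr;
    for (int s = 0; s < L.n; ++s)
      for (int a = 0; a < 4; ++a)
        for (int slot = 0; slot < 2; ++slot) {
          int i = L.idx(s, a, slot);
          if (L.T[i] == 0) continue;
          int g = gsucc(L.rows, L.cols, s, a);
          int sp = slot == 0 ? g : s;
          if (slot == 0 && (g < 0 || g == s)) continue;
          vs.push_back(s);
          va.push_back(a);
          vsp.push_back(sp);
          vn.push_back(L.T[i]);
          vr.push_back(L.Rm[i]);
          vterm.push_back(L.terminal[sp]);
        }
    return DataFrame::create(_["s"] = vs, _["a"] = va, _["sp"] = vsp,
                             _["n"] = vn, _["rmean"] = vr, _["terminal"] = vterm);
  }

  void importModel(int lev, IntegerVector s, IntegerVector a, IntegerVector sp,
                   IntegerVector n, NumericVector rmean, IntegerVector term) {
    Level& L = levels[lev];
    for (int i = 0; i < s.size(); ++i) {
      int slot = slotOf(L, s[i], a[i], sp[i]);
      if (slot < 0) continue;
      int j = L.idx(s[i], a[i], slot);
      L.T[j] = n[i];
      L.Rm[j] = rmean[i];
      if (term[i]) L.terminal[sp[i]] = 1;
    }
  }

  DataFrame exportRdist() {
    const Level& L = levels[0];
    std::vector<int> vs, va, vsp, vc;
    std::vector<double> vr;
    if (L.rdist)
      for (int s = 0; s < L.n; ++s)
        for (int a = 0; a < 4; ++a)
          for (int slot = 0; slot < 2; ++slot) {
            int i = L.idx(s, a, slot);
            int g = gsucc(L.rows, L.cols, s, a);
            int sp = slot == 0 ? g : s;
            if (slot == 0 && (g < 0 || g == s)) continue;
            for (size_t k = 0; k < rvals.size(); ++k)
              if (L.rcnt[i][k] > 0) {
                vs.push_back(s);
                va.push_back(a);
                vsp.push_back(sp);
                vr.push_back(rvals[k]);
                vc.push_back(L.rcnt[i][k]);
              }
          }
    return DataFrame::create(_["s"] = vs, _["a"] = va, _["sp"] = vsp,
                             _["reward"] = vr, _["count"] = vc);
  }

  double historyLik(IntegerVector s, IntegerVector a, IntegerVector sp,
                    NumericVector r) {
    std::vector<int> vs(s.begin(), s.end()), va(a.begin(), a.end()),
        vsp(sp.begin(), sp.end());
    std::vector<double> vr(r.begin(), r.end());
    return std::exp(historyLogProb(vs, va, vsp, vr));
  }
};

// ---------------- context bank ----------------

class ContextBank {
public:
  List mazeL, levelsL, cfgL;
  std::vector<std::unique_ptr<NavAgent>> agents;
  int active = 0;
  int m = 10;
  double threshold = 0.5, temperature = 1.0;
  long long bank_accesses = 0;
  // ring buffer
  std::vector<int> hs, ha, hsp;
  std::vector<double> hr;
  int n_switches = 0, n_creations = 0, n_discards = 0;
  // per-trial disappointment flags: contexts whose reward expectation has
  // already failed since the last reward / trial start
  std::vector<uint8_t> sad;

  ContextBank(List mazeL_, List levelsL_, List cfgL_)
      : mazeL(mazeL_), levelsL(levelsL_), cfgL(cfgL_) {
    m = as<int>(cfgL["history_m"]);
    threshold = as<double>(cfgL["new_context_threshold"]);
    temperature = as<double>(cfgL["temperature"]);
    agents.emplace_back(new NavAgent(mazeL, levelsL, cfgL));
    sad.assign(1, 0);
  }

  int nContexts() const { return (int)agents.size(); }
  int activeContext() const { return active; }
  NavAgent* agent(int k) { return agents[k].get(); }

  void clearHistory() {
    hs.clear();
    ha.clear();
    hsp.clear();
    hr.clear();
  }

  void pushHistory(int s, int a, int sp, double r) {
    hs.push_back(s);
    ha.push_back(a);
    hsp.push_back(sp);
    hr.push_back(r);
    if ((int)hs.size() > m) {
      hs.erase(hs.begin());
      ha.erase(ha.begin());
      hsp.erase(hsp.begin());
      hr.erase(hr.begin());
    }
  }

  // unsigned reward-prediction violation: an expected reward fails to appear
  // (disappointment, sign -1) or reward appears where none was expected
  // (recognition event, sign +1); 0 when the model's expectation is met or
  // the transition is unknown
  int surpriseSign(int k, int s, int a, int sp, double r) {
    NavAgent* ag = agents[k].get();
    const Level& L = ag->levels[0];
    int slot = ag->slotOf(L, s, a, sp);
    if (slot < 0) return 0;
    int i = L.idx(s, a, slot);
    bank_accesses += 2;
    if (L.T[i] == 0) return 0;
    if (L.Rm[i] > 0 && r <= 0) return -1;
    if (L.Rm[i] <= 0 && r > 0) return +1;
    return 0;
  }

  bool surprise(int k, int s, int a, int sp, double r) {
    return surpriseSign(k, s, a, sp, r) != 0;
  }

  // does any stored context explain this reward at this place? Explanation
  // requires direct evidence — the context must itself have experienced
  // reward r at sp (smoothed probabilities alone are too easily dragged
  // under or over a fixed threshold by incidental counts). Among explainers
  // the one with the highest aggregated reward probability is returned;
  // pmax is 1 when an explainer exists, else 0.
  int bestExplainer(int sp, double r, double& pmax) {
    pmax = 0.0;
    int best = -1;
    double score = -1.0;
    for (int k = 0; k < nContexts(); ++k) {
      bank_accesses += 2;
      if (agents[k]->rewardCountAt(sp, r) < 1) continue;
      double p = agents[k]->rewardProbState(sp, r);
      if (p > score) { score = p; best = k; pmax = 1.0; }
    }
    return best;
  }

  void createContext(int cur_base) {
    agents.emplace_back(new NavAgent(mazeL, levelsL, cfgL));
    sad.push_back(0);
    active = (int)agents.size() - 1;
    ++n_creations;
    clearHistory();
    anchorActive(cur_base);
  }

  // discard a never-rewarded hypothesis context (index k != active)
  void discardContext(int k) {
    agents.erase(agents.begin() + k);
    sad.erase(sad.begin() + k);
    if (active > k) --active;
    ++n_discards;
  }

  void clearSad() { std::fill(sad.begin(), sad.end(), 0); }

  void anchorActive(int s) {
    NavAgent* ag = agents[active].get();
    for (int k = 0; k < ag->nLevels(); ++k) {
      ag->levels[k].cur_macro = ag->absmap[k][s];
      ag->levels[k].accum = 0.0;
      ag->levels[k].prev_macro = -1;
    }
  }

  // softmax switch over window log-likelihoods, optionally restricted to a
  // candidate subset; returns true when the active context changed
  bool softmaxSwitch(const std::vector<int>* restrict = nullptr) {
    if (hs.empty() || nContexts() < 2) return false;
    std::vector<double> logp;
    gScores(logp);
    std::vector<int> cand;
    if (restrict) cand = *restrict;
    else for (int k = 0; k < nContexts(); ++k) cand.push_back(k);
    if (cand.empty()) return false;
    if (!restrict) {
      int best = cand[0];
      for (int k : cand)
        if (logp[k] > logp[best]) best = k;
      if (best == active) return false;
    }
    double mx = logp[cand[0]];
    for (int k : cand) mx = std::max(mx, logp[k]);
    double tot = 0.0;
    std::vector<double> w(cand.size());
    for (size_t i = 0; i < cand.size(); ++i) {
      w[i] = std::exp((logp[cand[i]] - mx) / temperature);
      tot += w[i];
    }
    double u = unif_rand() * tot, cum = 0.0;
    int pick = cand.back();
    for (size_t i = 0; i < cand.size(); ++i) {
      cum += w[i];
      if (u <= cum) { pick = cand[i]; break; }
    }
    if (pick == active) return false;
    active = pick;
    ++n_switches;
    clearHistory();
    return true;
  }

  // per-context geometric-mean experience likelihood over the buffer
  std::vector<double> gScores(std::vector<double>& logp) {
    int K = nContexts();
    logp.assign(K, 0.0);
    std::vector<double> g(K, 1.0);
    int len = (int)hs.size();
    if (len == 0) return g;
    for (int k = 0; k < K; ++k) {
      logp[k] = agents[k]->historyLogProb(hs, ha, hsp, hr);
      bank_accesses += 2 * len;
      g[k] = std::exp(logp[k] / len);
    }
    return g;
  }

  NumericVector historyG() {
    std::vector<double> logp;
    std::vector<double> g = gScores(logp);
    return NumericVector(g.begin(), g.end());
  }

  void observeAs(int k, int s, int a, int sp, double r, bool term) {
    agents[k]->modelObserve(0, s, a, sp, r, term);
  }

  void pushExperience(int s, int a, int sp, double r) { pushHistory(s, a, sp, r); }

  // routine (no-surprise) evaluation: softmax switch when the active context
  // no longer best explains the history window
  List evaluateNow() {
    RNGScope scope;
    bool changed = softmaxSwitch();
    return List::create(_["changed"] = changed, _["active"] = active);
  }

  NumericVector explainers(int s, int a, int sp, double r) {
    NumericVector out(nContexts());
    for (int k = 0; k < nContexts(); ++k)
      out[k] = agents[k]->rewardProbState(sp, r);
    return out;
  }

  int surpriseSignR(int k, int s, int a, int sp, double r) {
    return surpriseSign(k, s, a, sp, r);
  }

  DataFrame contextModel(int k, int lev) { return agents[k]->exportModel(lev); }

  int nSwitches() const { return n_switches; }
  IntegerVector creationCounts() const {
    return IntegerVector::create(n_creations, n_discards);
  }

  long long totalAccesses() {
    long long t = bank_accesses;
    for (auto& a : agents) t += a->accesses;
    return t;
  }

  List runTrials(int ntrials, int cap, IntegerVector goals) {
    RNGScope scope;
    IntegerVector steps(ntrials), ctx(ntrials), nctx(ntrials);
    NumericVector acc(ntrials);
    LogicalVector reached(ntrials);
    for (int tr = 0; tr < ntrials; ++tr) {
      int goal = goals.size() > 0 ? goals[tr % goals.size()] : -1;
      for (auto& ag : agents)
        if (goal >= 0) ag->setGoal(goal);
      NavAgent* ag = agents[active].get();
      int s = ag->maze.start;
      for (auto& a2 : agents) a2->resetEpisode();
      clearSad();
      int n = 0;
      bool ok = false;
      while (n < cap) {
        ag = agents[active].get();
        if (goal >= 0) ag->setGoal(goal);
        int planned;
        int a = ag->actInternal(s, planned);
        List e = ag->envStep(s, a);
        int sp = as<int>(e["sp"]);
        double r = as<double>(e["r"]);
        bool term = as<bool>(e["term"]);
        int sgn = surpriseSign(active, s, a, sp, r);
        pushHistory(s, a, sp, r);
        double pmax;
        if (sgn < 0) {
          // disappointment: an expected reward failed to appear here. The
          // active context's hypothesis about today is wrong; hand control
          // to a stored context not yet disappointed this trial (softmax
          // over history likelihoods). When every stored context has
          // already been disappointed, the situation is novel: a fresh
          // context is created and explores ("global remapping").
          sad[active] = 1;
          std::vector<int> cand;
          for (int k = 0; k < nContexts(); ++k)
            if (!sad[k]) cand.push_back(k);
          if (cand.empty()) createContext(sp);
          else if (softmaxSwitch(&cand)) anchorActive(sp);
        } else if (r > 0 && !agents[active]->believesRewardAt(sp)) {
          // recognition: reward appeared at a place the active context does
          // not believe rewarding. Reassign before recording so the reward
          // lands in the context that expects reward at this place; an
          // unidentified hypothesis context that is abandoned here is
          // discarded. When no stored context expects it, the active
          // context claims the site if still unidentified, else a fresh
          // context is created.
          int ex = bestExplainer(sp, r, pmax);
          if (pmax >= threshold && ex != active) {
            int old = active;
            bool husk = !agents[old]->has_reward;
            active = ex;
            ++n_switches;
            clearHistory();
            anchorActive(s);
            if (husk) discardContext(old);
          } else if (pmax < threshold && agents[active]->has_reward) {
            createContext(s);
          }
        } else if ((int)hs.size() >= m && agents[active]->has_reward) {
          // routine reconsideration; suspended while the active context is
          // an unidentified exploring hypothesis (stored contexts always
          // explain familiar corridors better, and handing control back to
          // them would re-enter the set that was just disappointed)
          if (softmaxSwitch()) anchorActive(s);
        }
        if (r > 0) clearSad();
        // the (possibly re-selected) active context records the experience
        // through its full hierarchy; non-positive experiences — shared
        // geometry and reward absence — are also recorded in every other
        // context's base model, so contexts differ only in where reward is
        ag = agents[active].get();
        if (goal >= 0) ag->setGoal(goal);
        ag->onStep(s, a, sp, r, term);
        if (r <= 0)
          for (int k = 0; k < nContexts(); ++k) {
            if (k == active) continue;
            // a context's own reward expectations are its identity: absence
            // evidence is not shared into places it believes rewarding
            NavAgent* o = agents[k].get();
            if (o->believesRewardAt(sp)) continue;
            o->modelObserve(0, s, a, sp, r, false);
          }
        ++n;
        if (term) { ok = true; break; }
        s = sp;
      }
      steps[tr] = n;
      ctx[tr] = active;
      nctx[tr] = nContexts();
      acc[tr] = (double)totalAccesses();
      reached[tr] = ok;
    }
    return List::create(_["steps"] = steps, _["accesses"] = acc,
                        _["reached"] = reached, _["context"] = ctx,
                        _["n_contexts"] = nctx);
  }
};

RCPP_MODULE(hipporl_module) {
  class_<NavAgent>("NavAgent")
      .constructor<List, List, List>()
      .method("nLevels", &NavAgent::nLevels)
      .method("setGoal", &NavAgent::setGoal)
      .method("setWalls", &NavAgent::setWalls)
      .method("accessCount", &NavAgent::accessCount)
      .method("modelObserve", &NavAgent::modelObserve)
      .method("transitionProb", &NavAgent::transitionProb)
      .method("experienceProb", &NavAgent::experienceProb)
      .method("predictedSuccessor", &NavAgent::predictedSuccessor)
      .method("backup", &NavAgent::backup)
      .method("sweep", &NavAgent::sweep)
      .method("queueSize", &NavAgent::queueSize)
      .method("tdUpdate", &NavAgent::tdUpdate)
      .method("selectGoal", &NavAgent::selectGoal)
      .method("lastPlanLevel", &NavAgent::lastPlanLevel)
      .method("planRoute", &NavAgent::planRoute)
      .method("act", &NavAgent::act)
      .method("envStep", &NavAgent::envStep)
      .method("onStep", &NavAgent::onStep)
      .method("resetEpisode", &NavAgent::resetEpisode)
      .method("runTrials", &NavAgent::runTrials)
      .method("qValues", &NavAgent::qValues)
      .method("setQValue", &NavAgent::setQValue)
      .method("levelDims", &NavAgent::levelDims)
      .method("parentMap", &NavAgent::parentMap)
      .method("exportModel", &NavAgent::exportModel)
      .method("importModel", &NavAgent::importModel)
      .method("exportRdist", &NavAgent::exportRdist)
      .method("historyLik", &NavAgent::historyLik);
  class_<ContextBank>("ContextBank")
      .constructor<List, List, List>()
      .method("nContexts", &ContextBank::nContexts)
      .method("activeContext", &ContextBank::activeContext)
      .method("historyG", &ContextBank::historyG)
      .method("observeAs", &ContextBank::observeAs)
      .method("pushExperience", &ContextBank::pushExperience)
      .method("evaluateNow", &ContextBank::evaluateNow)
      .method("totalAccesses", &ContextBank::totalAccesses)
      .method("runTrials", &ContextBank::runTrials)
      .method("surprise", &ContextBank::surprise)
      .method("surpriseSign", &ContextBank::surpriseSignR)
      .method("explainers", &ContextBank::explainers)
      .method("nSwitches", &ContextBank::nSwitches)
      .method("contextModel", &ContextBank::contextModel)
      .method("creationCounts", &ContextBank::creationCounts);
}
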