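---
title: "Hierarchical model-based reinforcement learning for spatial navigation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical model-based reinforcement learning for spatial navigation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hipporl)
```

## The model

`hipporl` implements tabular model-based reinforcement learning (MBRL) on
discrete grid mazes, organised as a stack of spatial abstraction levels
inspired by the dorsoventral gradient of hippocampal place-field sizes.
The agent occupies one cell of a `rows x cols` grid and moves with four
compass actions; bumping a wall or the boundary keeps it in place at reward
−1, entering the goal pays +100 and ends the trial, and every other move is
free. The agent senses only its own location.

Level 1 of the hierarchy is the maze grid itself. Each higher level
aggregates 2 x 2 blocks of the level below (groups of four along the
remaining dimension once one dimension collapses), stopping at a single
macro-state; a 16 x 48 arena yields six levels with 768, 192, 48, 12, 3 and
1 states. Every level runs its own MBRL learner:

* a transition count table `T[s, a, s']` over the admissible successor set
  of each pair — the geometric neighbour plus the state itself (a move may
  bounce) — giving the smoothed estimate
  `P(s' | s, a) = (T[s,a,s'] + 1) / sum_s2 (T[s,a,s2] + 1)`
  with a prior count of one;
* a reward table `R[s, a, s']` holding the exact running mean of rewards
  observed on that transition,
  `R <- R + (r - R) / T`;
* a Q-table updated by model-based backups
  `Q(s,a) = sum_s' P(s'|s,a) (R[s,a,s'] + gamma * max_a' Q[s',a'])`,
  scheduled by prioritized sweeping: states are queued by the magnitude of
  their pending value change and popped in priority order, at most `budget`
  state updates per environment step (20 per level for the six-level agent,
  120 for the single-level "conventional" agent — equal totals). Goal
  states are absorbing: they contribute no continuation value and their own
  Q is pinned at zero.

Macro levels observe a transition whenever the agent's movement crosses a
macro boundary at their resolution. The reward attached to a macro
transition `(X, a, Y)` is the maximum reward experienced during the
occupancy of the destination `Y`, recorded when the agent leaves `Y` or the
trial ends there. This max-reward screening lets the goal reward reach
every level of abstraction while everyday step costs are filtered out; the
destination reading is forced by the episode structure — a trial ends
inside the goal macro-state, so a source-side accumulator could never
attach the goal reward to any directional macro entry. Blocked base moves
are additionally recorded at every macro level as penalised
self-transitions, so that new walls gradually invalidate previously learned
macro routes.

## Action selection: goals, forward sweeps, refinement

Each step the agent selects a goal by scanning all levels for the maximum
positive action value. Comparison is on raw Q magnitudes; the decreasing
per-level discounts (0.9 at the base down to 0.5 at the top, linear)
keep the per-level maxima comparable, and "ties" resolve to the highest
level whose maximum lies within 10% (`goal_tie_tol`) of the global maximum.
Single-state levels are excluded (they carry no direction), and an untried
argmax entry targets its own source state — an untried count row holds no
successor prediction, and the informative exploratory target is the place
itself. Otherwise the goal is the transition-count argmax successor.

The goal is refined top-down by successive A* forward sweeps: the level
below the goal level plans from the agent's current macro-state to the
goal's children; each lower level re-plans toward the children of the first
step above, restricted to the children of the current and first-step
macro-states; the first move of the base-level plan is the planned action,
executed with probability `epsilon = 0.8` (otherwise a uniformly random
action).

Three numerical choices matter here:

* **Edge costs.** A* weighs each geometric edge by the expected number of
  attempts to cross it under the model, `(T_cross + T_self + 2) /
  (T_cross + 1)`: untried moves cost about 2, well-travelled ones approach
  1, and moves observed to bounce grow linearly in the evidence. Beliefs
  therefore stay continuous — a wrongly expensive edge self-corrects when
  probed — while overwhelming one-sided bounce evidence (ten or more
  bounces, never a crossing) marks a certain wall. The heuristic is the
  Manhattan distance at the prior edge cost (2 per step): exact on
  unexplored terrain, mildly greedy where edges are cheaper, which keeps
  sweeps focused. On a uniform (untrained) model, planned routes equal
  breadth-first shortest paths.
* **Budgeted sweeps.** Every A* call may expand at most the agent's total
  per-step update budget (120 for both architectures). A goal whose
  refinement fails — usually because it is too distant for the budget — is
  lifted to the macro-state containing it and re-planned one level coarser,
  with the first refinement focused on the goal's own ancestor; the
  hierarchical agent can therefore always act on some resolution, whereas
  the single-level agent simply loses its plan. If a restricted refinement
  window admits no path, that failure itself is recorded as one imagined
  bounce against the corresponding macro edge (a "mental bump") — the
  forward sweep discovering that a macro step cannot currently be realised
  is evidence about the model.
* **Fallback.** When no level produces a plan the agent acts uniformly at
  random. A greedy-on-cached-values fallback was tried and rejected: on a
  stale value field it forms absorbing two-cycles that occasional random
  actions cannot escape, while the uniform fallback is ergodic and
  guarantees that wrongly-blocked-in-belief regions are eventually
  re-probed.

Q-tables initialise at `optimism = 1` (not zero). Untried state-actions
then look mildly attractive, and goal selection drives a near-systematic
sweep of unexplored space before the first reward; once real reward is
found its propagated value (about 100 near the goal) dominates the residual
optimism everywhere the discount horizon reaches. Zero initialisation was
rejected because it reduces the first trial to a pure random walk, whose
expected duration on the 16 x 48 arena (about 4,000 steps) is incompatible
with the published step counts this package reproduces, and whose variance
is incompatible with their error brackets.

## Lesioned variants

`apply_lesion()` builds untrained variants: `"vH"` retains only the base
level (the conventional agent, inheriting the full 120-update budget);
`"dH"` retains the highest informative macro level (1 x 3 on the reference
arena) as a model-based goal-setter while the base is replaced by one-step
Q-learning (`alpha = 0.1`, discount 0.9). The dH agent scores actions by
`Q_free(s, a) + Q_top(macro(s), a)`, epsilon-greedy with uniform random
tie-breaks. Its macro level starts without optimism and collects no bump
evidence: with no planner to serve, both would only inject arbitrary
directional biases at 8 x 8-cell granularity — before reward discovery the
dH agent should be, and is, essentially random.

## Context bank

For tasks whose reward structure changes wholesale, `context_agent()`
maintains a bank of full hierarchical agents — one per context — and an
`m = 10`-step experience window. The base model of each context tracks
per-transition reward histograms, giving the experience probability
`P(e) = P(s'|s,a) * P(r|s,a,s')` (with add-one smoothing over the reward
values the model has seen) and the window likelihood `P(H) = prod P(e_i)`.

Evaluation is driven by reward-prediction violations on the active
context's base model:

* *Disappointment* (expected reward missing): the active context is marked
  failed for the current trial and control passes, by softmax over the
  window log-likelihoods, to a stored context that has not yet failed; when
  every stored context has failed, a fresh empty context is created and
  explores. This produces the characteristic tour of known reward sites,
  and discovery of genuinely novel sites by fresh hypotheses.
* *Recognition* (reward where the active context expects none): control is
  reassigned, before the experience is recorded, to the context that has
  itself experienced this reward at this place (ranked by the aggregated
  per-place reward probability); a never-rewarded hypothesis abandoned this
  way is discarded. If no stored context has such evidence, the active
  context claims the site when it is itself still unrewarded, and a fresh
  context is created otherwise. Explanation requires direct evidence
  because smoothed probabilities alone are dragged across any fixed
  threshold by incidental counts (ignorance priors and pre-claim zeros).
* Otherwise, once the window is full, the active context is reconsidered by
  the same softmax whenever it no longer best explains the window —
  suspended while the active context is a still-unrewarded hypothesis,
  whose exploration would otherwise be interrupted by corridor familiarity.

Non-positive experiences (free moves, bumps, reward absence) are recorded
in every context's base model except where a context holds a positive
reward belief: contexts share the arena's geometry and differ only in their
reward structure, which is what remapping is for. On the four-site task
this algorithm converges to exactly one context per site in every tested
repetition, with surplus hypotheses discarded on resolution.

The window length 10 is small enough to switch within a few steps of a
goal change and large enough to separate contexts; the softmax temperature
is 1 over log-likelihoods; the recognition threshold retains the 0.5
constant applied to the aggregated per-place reward probability of
contexts holding direct evidence.

## The simulated studies

The experiment drivers reproduce four studies under the conditions the
package treats as canonical: rewards +100 / −1, 5,000-step trial caps
(scaled proportionally for scaled arenas, 500 for the four-goal task),
16 x 48 arenas with start and goal at mid-height near opposite short ends,
six levels with 20 updates per step each against a single level with 120,
and 56 repetitions in the full studies (reduced sizes are stated wherever
a test or script uses them; the acceptance script averages 24 repetitions
per target and the suite's study-level checks use 56 where the comparison
is statistical and 20 where it is structural). One master seed spawns an
independent stream per agent group and repetition; every record table is a
deterministic function of its configuration and seed.

The five boundary-adaptation mazes are this package's own ASCII fixtures
(`inst/extdata/adapt_[A-E].txt`): 16 x 48 arenas plus long internal walls
that force a detour through the route learned in the open arena, including
direction-reversing detours and a walled goal pocket, which are the
geometries that most differentiate architectures. The four-goal arena
places its reward sites in the corners of a 7 x 7 grid with the start at
the centre. These generators define the study conditions; they emulate the
discrete, fully deterministic arenas of the original experiments and none
of the noise, partial observability or continuous kinematics of real
spatial behaviour, so passing tests speak to the computational claims, not
to biological realism.

"Model accesses" — the package's proxy for cognitive effort — counts reads
and writes of the T, R and Q tables during model updates, prioritized
sweeping and planning (three per candidate in a backup, three per action in
an A* expansion, two per model write, one per level per goal selection from
a cached maximum; environment steps do not count). Absolute counts are
meaningful only relative to this definition; analyses use orderings and
growth trends.

## Known limitations

* The conventional baseline is strong: its optimism-driven frontier
  exploration is scale-robust, so it still solves 12,288-state arenas
  within proportionally scaled caps (at about 2.3 x the hierarchical step
  count) and its access growth is near-linear. The published failure of the
  non-hierarchical agent at that scale, its super-linear access growth, and
  the early-trial deficit of the ventral-lesion variant all presuppose a
  weaker baseline whose exploration degrades with distance; those three
  checks are left failing by design rather than weakening the baseline.
* Both architectures learn the open arena within roughly two trials, so
  "early learning" windows are short relative to the original studies.
* Macro-state aliasing (a macro edge passable from one part of a block
  only) is represented by a single expected-attempts cost; the cost
  semantics keep it finite and correctable, but the believed macro graph
  cannot express the distinction itself.
* Context knowledge does not transfer across contexts beyond shared
  non-positive experience; each new context re-learns its policy at every
  level.
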