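# hipporl

Hierarchical model-based reinforcement learning (MBRL) for spatial
navigation on discrete grid mazes, inspired by the computational properties
of the hippocampus: a multi-resolution representation of space (the
dorsoventral gradient of place-field sizes), forward-sweep route planning,
and context-driven global remapping.

## Who this is for

Computational-neuroscience and reinforcement-learning researchers who want
a reproducible, fully seeded implementation of hierarchical tabular MBRL
for goal-directed foraging — including the classic comparisons against a
single-level ("conventional") agent, simulated dorsal/ventral hippocampal
lesions, adaptation to sudden boundary changes, probabilistic reward
contexts, and scaling to large arenas.

## The model in brief

An agent moves on a `rows x cols` grid with four compass actions (wall
bumps: reward −1, stay in place; goal: reward +100, trial ends; otherwise
0). Space is recursively aggregated into 2 x 2 macro-states — a 16 x 48
arena yields six levels with 768, 192, 48, 12, 3 and 1 states — and each
level runs its own tabular MBRL learner:

- smoothed transition model `P(s'|s,a) = (T[s,a,s'] + 1) / Σ(T[s,a,s2] + 1)`
  over the admissible successors (neighbour plus self), prior count 1;
- reward table `R[s,a,s']` as an exact running mean,
  `R ← R + (r − R)/T`; macro levels record the *maximum* reward of a
  macro-state occupancy;
- action values by model-based backups
  `Q(s,a) = Σ P(s'|s,a)(R[s,a,s'] + γ max Q[s',·])`, scheduled with
  prioritized sweeping under a per-step budget (20 per level hierarchical,
  120 conventional), per-level discounts decreasing 0.9 → 0.5.

Goals are chosen by the maximum action value across levels and refined
top-down by successive budgeted A* forward sweeps; the planned action is
executed ε-greedily (ε = 0.8). A likelihood-based context bank
(`P(H) = Π P(s'|s,a) P(r|s,a,s')` over the recent-experience window)
stores one full agent per reward context and remaps on reward-prediction
violations. Lesioned variants remove parts of the stack (`vH`: base level
only; `dH`: top level plus a model-free Q-learning base).

## Worked example

```r
library(hipporl)

arena <- make_open_arena(16, 48)
arena
#> <grid_maze> 16 x 48 (768 free states), start (9,3), goal (9,46), cap 5000

set.seed(1)
agent <- nav_agent(arena, budgets = 20)
agent
#> <nav_agent> 6 level(s): 16x48 > 8x24 > 4x12 > 2x6 > 1x3 > 1x1; lesion: none

run_trials(agent, 5)
#>   trial steps accesses reached
#> 1     1  1074  1535217    TRUE
#> 2     2    47  1699128    TRUE
#> 3     3    59  1902748    TRUE
#> 4     4    73  2157891    TRUE
#> 5     5    63  2364871    TRUE
```

Trial 1 is the systematic exploration of the unknown arena (1,074 steps to
the first goal); from trial 2 the agent navigates near-optimally (the
shortest route is 43 steps; ε-greedy execution adds ~20% detours).
`accesses` counts cumulative reads/writes of the model tables — the
package's proxy for cognitive effort. After learning, goal selection sits
at an abstract level:

```r
select_goal(agent)
#> $found  TRUE
#> $level  3        # 4 x 12 macro-grid
#> $goal   36       # the macro-state containing the goal cell
```

Experiment drivers reproduce the four studies and return tidy per-trial
records:

```r
lesion  <- run_lesion_experiment(reps = 8, seed = 1)     # intact vs vH vs dH
adapt   <- run_adaptation_experiment("D", reps = 8)      # boundary change
context <- run_context_experiment(reps = 8)              # 4 reward sites
scaling <- run_scaling_experiment(c(1, 1.5, 2), reps = 5)
summarize_trials(adapt)                                  # means + 2.5/97.5%
```

A thin command-line wrapper is installed as `exec/hipporl`:

```sh
Rscript exec/hipporl run adapt --variant D --reps 8 --seed 1 --out results/
```

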