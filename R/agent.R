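#' Create a hierarchical model-based navigation agent
#'
#' The agent maintains one tabular world model and Q-table per abstraction
#' level (see [build_hierarchy()]). After every environment step each level
#' that registered a state transition updates its model and runs prioritized
#' sweeping within its per-step budget; actions are chosen by cross-level
#' goal selection followed by successive A* refinement, executed epsilon-
#' greedily (the planned action is taken with probability `epsilon`).
#'
#' Q-tables are initialised to `optimism` (> 0), so untried state-actions
#' look mildly attractive and goal selection drives a systematic sweep of
#' unexplored space before the first reward is found; once real reward is
#' observed its value dominates.
#'
#' @param maze a [grid_maze()].
#' @param n_levels number of abstraction levels to keep, counted from the
#'   base; `NULL` (default) keeps the full hierarchy.
#' @param discounts per-level discount factors; default
#'   [discount_schedule()] over the kept levels.
#' @param budgets per-level prioritized-sweeping budgets (model updates per
#'   environment step); recycled; default 20 per level.
#' @param epsilon probability of executing the planned action (default 0.8).
#' @param optimism initial Q value (default 1).
#' @param priority_threshold minimum priority queued for sweeping.
#' @param goal_tie_tol relative tolerance for cross-level goal ties: the
#'   goal is set at the highest level whose maximum action value is within
#'   this fraction of the global maximum (default 0.1, about the scale of
#'   the transition-smoothing noise on well-visited entries).
#' @param reward_dist keep per-transition reward histograms at the base
#'   level (needed for context likelihoods).
#' @param alpha learning rate of the model-free base used by the
#'   dorsal-lesion variant (ignored otherwise).
#' @return An object of class `nav_agent`.
#' @export
nav_agent <- function(maze, n_levels = NULL, discounts = NULL, budgets = 20,
                      epsilon = 0.8, optimism = 1, priority_threshold = 1e-4,
                      goal_tie_tol = 0.1, reward_dist = FALSE, alpha = 0.1) {
  hier <- build_hierarchy(maze)
  if (is.null(n_levels)) n_levels <- length(hier)
  n_levels <- min(n_levels, length(hier))
  hier <- hier[seq_len(n_levels)]
  if (is.null(discounts)) discounts <- discount_schedule(n_levels)
  discounts <- rep_len(discounts, n_levels)
  budgets <- rep_len(as.integer(budgets), n_levels)
  specs <- lapply(seq_len(n_levels), function(k) {
    lv <- list(rows = hier[[k]]$rows, cols = hier[[k]]$cols,
               gamma = discounts[k], budget = budgets[k], model_based = TRUE)
    if (k > 1L) lv$up <- hier[[k]]$up - 1L
    lv
  })
  cfg <- list(epsilon = epsilon, optimism = optimism,
              priority_threshold = priority_threshold,
              goal_tie_tol = goal_tie_tol, alpha = alpha,
              reward_dist = reward_dist)
  new_nav_agent(maze, specs, cfg, kind = "none")
}

# shared constructor used by nav_agent(), conventional_agent(), apply_lesion().
# agents are environments so that in-place updates (set_maze) stay visible to
# the caller, matching the reference semantics of the underlying engine.
new_nav_agent <- function(maze, specs, cfg, kind) {
  ptr <- new(NavAgent, maze_to_cpp(maze), specs, cfg)
  structure(list2env(list(ptr = ptr, maze = maze, specs = specs,
                          config = cfg, lesion = kind)),
            class = "nav_agent")
}

#' Conventional (non-hierarchical) model-based agent
#'
#' A single-level agent: the degenerate case of [nav_agent()] with only the
#' base level, conventionally granted the full per-step update budget.
#'
#' @inheritParams nav_agent
#' @param budget model updates per step (default 120).
#' @param gamma base discount (default 0.9).
#' @return A `nav_agent` with one level.
#' @export
conventional_agent <- function(maze, budget = 120, gamma = 0.9,
                               epsilon = 0.8, optimism = 1,
                               priority_threshold = 1e-4,
                               reward_dist = FALSE) {
  nav_agent(maze, n_levels = 1, discounts = gamma, budgets = budget,
            epsilon = epsilon, optimism = optimism,
            priority_threshold = priority_threshold,
            reward_dist = reward_dist)
}

#' @export
print.nav_agent <- function(x, ...) {
  dims <- vapply(x$specs, function(l) sprintf("%dx%d", l$rows, l$cols), "")
  cat(sprintf("<nav_agent> %d level(s): %s; lesion: %s\n",
              length(x$specs), paste(dims, collapse = " > "), x$lesion))
  invisible(x)
}

#' Number of abstraction levels of an agent
#' @param agent a `nav_agent`.
#' @return integer.
#' @export
n_levels <- function(agent) agent$ptr$nLevels()

#' Cumulative model accesses
#'
#' Count of reads/writes of the transition, reward and Q tables performed
#' during model updates, prioritized sweeping and planning — the package's
#' proxy for cognitive effort. Environment steps themselves do not count.
#'
#' @param agent a `nav_agent` or `context_agent`.
#' @return numeric count.
#' @export
model_accesses <- function(agent) {
  if (inherits(agent, "context_agent")) return(agent$ptr$totalAccesses())
  agent$ptr$accessCount()
}

#' Run complete trials of the navigation task
#'
#' Each trial starts at the maze's start cell and ends when the goal is
#' reached or the step cap is hit, after which the agent is relocated to the
#' start. Learning (model updates and sweeping) happens on every step.
#'
#' @param agent a `nav_agent` or `context_agent`.
#' @param n_trials number of trials.
#' @param step_cap per-trial cap; default the maze's `step_cap`.
#' @param goals optional per-trial goal state ids (recycled), overriding the
#'   maze goal — used by the probabilistic-reward task.
#' @return tibble with one row per trial: `trial`, `steps`, `accesses`
#'   (cumulative at trial end), `reached`, and for context agents `context`
#'   (active context at trial end, 1-based) and `n_contexts`.
#' @export
run_trials <- function(agent, n_trials, step_cap = NULL, goals = NULL) {
  if (is.null(step_cap)) step_cap <- agent$maze$step_cap
  g <- if (is.null(goals)) integer(0) else as.integer(goals) - 1L
  res <- agent$ptr$runTrials(as.integer(n_trials), as.integer(step_cap), g)
  out <- tibble::tibble(trial = seq_len(n_trials), steps = res$steps,
                        accesses = res$accesses, reached = res$reached)
  if (!is.null(res$context)) {
    out$context <- res$context + 1L
    out$n_contexts <- res$n_contexts
  }
  out
}

#' Choose an action at a base state
#'
#' Runs goal selection and the A* refinement cascade, then applies the
#' epsilon-greedy rule. Consumes random numbers from R's RNG.
#'
#' @param agent a `nav_agent`.
#' @param state base state id (1-based) or `c(row, col)`.
#' @return list with `planned` (action id or `NA` if no plan) and `action`
#'   (the action to execute, 1..4).
#' @export
agent_act <- function(agent, state) {
  s <- as_state_id(agent, state)
  r <- agent$ptr$act(s - 1L)
  list(planned = if (r[1] < 0) NA_integer_ else r[1] + 1L, action = r[2] + 1L)
}

#' Feed one observed transition through the hierarchy
#'
#' The base level records the experience directly; higher levels accumulate
#' the maximum reward seen within the current macro-state and record a macro
#' transition when the move crosses a macro boundary. Every level then runs
#' prioritized sweeping within its budget.
#'
#' @param agent a `nav_agent`.
#' @param state,next_state base state ids or `c(row, col)`.
#' @param action 1..4 or action name.
#' @param reward observed reward.
#' @param goal_reached whether the transition ended the trial.
#' @return the agent, invisibly.
#' @export
agent_observe <- function(agent, state, action, next_state, reward,
                          goal_reached = FALSE) {
  s <- as_state_id(agent, state)
  sp <- as_state_id(agent, next_state)
  agent$ptr$onStep(s - 1L, action_code(action) - 1L, sp - 1L, reward,
                   isTRUE(goal_reached))
  invisible(agent)
}

#' Reset per-episode bookkeeping after relocation
#' @param agent a `nav_agent`.
#' @return the agent, invisibly.
#' @export
reset_episode <- function(agent) {
  agent$ptr$resetEpisode()
  invisible(agent)
}

#' Replace the maze walls (and goal) of an existing agent
#'
#' Used by the boundary-adaptation experiment: the agent keeps everything it
#' has learned while the environment changes under it. Dimensions must match.
#'
#' @param agent a `nav_agent`.
#' @param maze a [grid_maze()] with the same dimensions.
#' @return the agent, invisibly.
#' @export
set_maze <- function(agent, maze) {
  stopifnot(maze$rows == agent$maze$rows, maze$cols == agent$maze$cols)
  agent$ptr$setWalls(maze_to_cpp(maze)$wall0)
  agent$ptr$setGoal(cell_id(maze, maze$goal) - 1L)
  agent$maze <- maze
  invisible(agent)
}

# ---- world-model surface -------------------------------------------------

#' Record an experience in one level's world model
#'
#' Low-level update of a single level: increments the transition count and
#' updates the running-mean reward (and the reward histogram when the
#' distribution variant is enabled). No sweeping is performed; see
#' [agent_observe()] for the full learning step.
#'
#' @param agent a `nav_agent`.
#' @param level level index, 1 = base.
#' @param s,sp level-state ids (1-based, row-major on the level grid).
#' @param a action 1..4 or name.
#' @param r reward.
#' @param terminal whether `sp` is reward-absorbing.
#' @return the agent, invisibly.
#' @export
model_observe <- function(agent, level, s, a, sp, r, terminal = FALSE) {
  agent$ptr$modelObserve(level - 1L, s - 1L, action_code(a) - 1L, sp - 1L,
                         r, isTRUE(terminal))
  invisible(agent)
}

#' Smoothed transition probability
#'
#' `P(sp | s, a) = (T[s,a,sp] + 1) / sum_s2 (T[s,a,s2] + 1)` over the
#' admissible successor set of `(s, a)` — the geometric neighbour plus the
#' state itself (a move may be blocked). Returns 0 for a state outside the
#' candidate set.
#'
#' @inheritParams model_observe
#' @return probability.
#' @export
transition_prob <- function(agent, level, s, a, sp) {
  agent$ptr$transitionProb(level - 1L, s - 1L, action_code(a) - 1L, sp - 1L)
}

#' Probability of a single experience under the base world model
#'
#' `P(e) = P(sp | s, a) * P(r | s, a, sp)`, the transition probability times
#' the add-one-smoothed empirical reward probability. Requires the agent to
#' have been built with `reward_dist = TRUE`.
#'
#' @inheritParams model_observe
#' @return probability.
#' @export
experience_prob <- function(agent, s, a, sp, r) {
  agent$ptr$experienceProb(s - 1L, action_code(a) - 1L, sp - 1L, r)
}

#' Most likely successor of a state-action pair
#'
#' Argmax of the transition counts; ties break to the lower state id, and a
#' fully untried pair falls back to the geometric neighbour.
#'
#' @inheritParams model_observe
#' @return level-state id.
#' @export
predicted_successor <- function(agent, level, s, a) {
  agent$ptr$predictedSuccessor(level - 1L, s - 1L, action_code(a) - 1L) + 1L
}

#' One model-based backup
#'
#' Expected value of `(s, a)` under the smoothed model:
#' `sum_sp P(sp|s,a) (R[s,a,sp] + gamma * max_a' Q[sp, a'])`, with terminal
#' successors contributing no continuation value. Pure: does not write Q.
#'
#' @inheritParams model_observe
#' @return backup value.
#' @export
backup_value <- function(agent, level, s, a) {
  agent$ptr$backup(level - 1L, s - 1L, action_code(a) - 1L)
}

#' Run prioritized sweeping at one level
#'
#' Pops up to `budget` states in priority order; each pop recomputes the
#' backups of all four actions and pushes predecessors whose implied value
#' change exceeds the priority threshold. Does nothing on an empty queue.
#'
#' @inheritParams model_observe
#' @param budget maximum number of state updates.
#' @return number of state updates performed.
#' @export
prioritized_sweep <- function(agent, level, budget) {
  agent$ptr$sweep(level - 1L, as.integer(budget))
}

#' @rdname prioritized_sweep
#' @return `sweep_queue_size()`: number of states currently queued.
#' @export
sweep_queue_size <- function(agent, level) agent$ptr$queueSize(level - 1L)

#' One-step temporal-difference (Q-learning) update
#'
#' `Q(s,a) <- Q(s,a) + alpha * (r + gamma * max_a' Q(sp,a') - Q(s,a))` on the
#' base-level table, as used by the model-free base of the dorsal-lesion
#' agent.
#'
#' @inheritParams model_observe
#' @export
q_learning_update <- function(agent, s, a, sp, r, terminal = FALSE) {
  agent$ptr$tdUpdate(s - 1L, action_code(a) - 1L, sp - 1L, r, isTRUE(terminal))
  invisible(agent)
}

#' Q-values of one level
#' @inheritParams model_observe
#' @return numeric `n x 4` matrix (columns up, down, left, right).
#' @export
q_values <- function(agent, level) {
  q <- agent$ptr$qValues(level - 1L)
  colnames(q) <- ACTIONS
  q
}

#' @rdname q_values
#' @param value new Q value.
#' @export
set_q <- function(agent, level, s, a, value) {
  agent$ptr$setQValue(level - 1L, s - 1L, action_code(a) - 1L, value)
  invisible(agent)
}

#' Level grid dimensions and base-to-level state map
#' @inheritParams model_observe
#' @return `level_dims()`: `c(rows, cols)`; `parent_map()`: integer vector
#'   mapping each base state id to its macro-state id at `level`.
#' @export
level_dims <- function(agent, level) agent$ptr$levelDims(level - 1L)

#' @rdname level_dims
#' @export
parent_map <- function(agent, level) agent$ptr$parentMap(level - 1L) + 1L

# ---- goal selection and planning ----------------------------------------

#' Select the current goal across all levels
#'
#' Scans the Q-tables of every model-based level for the maximum positive
#' action value (ties prefer higher levels); the goal is the state where
#' that action is expected to lead according to the transition counts.
#' Returns `found = FALSE` when no positive value exists anywhere.
#'
#' @param agent a `nav_agent`.
#' @return list with `found`, and when found: `level`, `source`, `action`,
#'   `goal` (level-state id).
#' @export
select_goal <- function(agent) {
  g <- agent$ptr$selectGoal()
  if (!g$found) return(list(found = FALSE))
  list(found = TRUE, level = g$level + 1L, source = g$source + 1L,
       action = g$action + 1L, goal = g$goal + 1L)
}

#' Plan a route at one level with A*
#'
#' A* over the level's transition graph: observed transitions plus untried
#' geometric moves assumed passable (moves only ever observed to bounce back
#' are treated as blocked). Unit edge costs; the heuristic is the minimum
#' Manhattan distance to any target; action values break ties between
#' equal-cost expansions.
#'
#' @inheritParams model_observe
#' @param source level-state id.
#' @param targets vector of level-state ids.
#' @return integer vector of level-state ids from `source` to the first
#'   target reached (length 1 if `source` is a target), or `NULL` when no
#'   path exists.
#' @export
plan_route <- function(agent, level, source, targets) {
  p <- agent$ptr$planRoute(level - 1L, source - 1L, as.integer(targets) - 1L)
  if (length(p) == 0L) return(NULL)
  p + 1L
}

# ---- serialization -------------------------------------------------------

#' Export a level's world model as a table
#'
#' One row per observed `(s, a, sp)` with its count, running-mean reward and
#' terminal flag. [load_world_model()] restores such a table into an agent,
#' and `write_world_model()` / `read_world_model()` round-trip it through a
#' plain TSV file.
#'
#' @inheritParams model_observe
#' @return tibble with columns `s`, `a`, `sp`, `n`, `rmean`, `terminal`.
#' @export
world_model <- function(agent, level = 1) {
  d <- agent$ptr$exportModel(level - 1L)
  tibble::tibble(s = d$s + 1L, a = d$a + 1L, sp = d$sp + 1L, n = d$n,
                 rmean = d$rmean, terminal = as.logical(d$terminal))
}

#' @rdname world_model
#' @param model a table as returned by `world_model()`.
#' @export
load_world_model <- function(agent, model, level = 1) {
  agent$ptr$importModel(level - 1L, model$s - 1L, model$a - 1L,
                        model$sp - 1L, as.integer(model$n), model$rmean,
                        as.integer(model$terminal))
  invisible(agent)
}

#' @rdname world_model
#' @param path file path.
#' @export
write_world_model <- function(agent, path, level = 1) {
  write.table(as.data.frame(world_model(agent, level)), path, sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname world_model
#' @export
read_world_model <- function(path) {
  tibble::as_tibble(read.delim(path, sep = "\t"))
}

#' Reward histogram of the base model (distribution variant)
#' @param agent a `nav_agent` built with `reward_dist = TRUE`.
#' @return tibble with columns `s`, `a`, `sp`, `reward`, `count`.
#' @export
reward_histogram <- function(agent) {
  d <- agent$ptr$exportRdist()
  tibble::tibble(s = d$s + 1L, a = d$a + 1L, sp = d$sp + 1L,
                 reward = d$reward, count = d$count)
}

#' Likelihood of an experience history under the base world model
#'
#' Product of [experience_prob()] over the rows of `history`; 1 for an empty
#' history.
#'
#' @param agent a `nav_agent` with `reward_dist = TRUE`.
#' @param history data frame with columns `s`, `a`, `sp`, `r` (1-based state
#'   ids and action codes).
#' @return probability.
#' @export
history_likelihood <- function(agent, history) {
  if (NROW(history) == 0L) return(1)
  agent$ptr$historyLik(history$s - 1L, as.integer(history$a) - 1L,
                       history$sp - 1L, as.numeric(history$r))
}

# accept either a 1-based row-major state id or c(row, col)
as_state_id <- function(agent, state) {
  if (length(state) == 2L && !is.null(agent$maze))
    return(cell_id(agent$maze, as.integer(state)))
  as.integer(state)
}
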