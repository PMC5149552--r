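#' Context-switching hierarchical agent
#'
#' Wraps a bank of full hierarchical agents, one per learned context, plus a
#' ring buffer of the `m` most recent experiences. Context evaluation is
#' driven by reward-prediction violations on the active context's base world
#' model:
#'
#' * a *disappointment* (expected reward missing) marks the active context as
#'   failed for the current trial and hands control to a stored context not
#'   yet disappointed, drawn from a softmax over the Eq.-5 history
#'   log-likelihoods; when every stored context has failed, a fresh empty
#'   context is created and explores ("global remapping");
#' * a *recognition* event (reward at a place the active context does not
#'   believe rewarding) reassigns control to the context whose base model
#'   gives the observed reward probability at least
#'   `new_context_threshold` at that place, before the experience is
#'   recorded; a never-rewarded hypothesis context abandoned this way is
#'   discarded, and when no stored context expects the reward a fresh
#'   context claims it;
#' * otherwise, once the buffer is full, the active context is reconsidered
#'   by the same softmax whenever it is no longer the best explanation of
#'   the history (suspended while the active context is a still-unrewarded
#'   exploring hypothesis).
#'
#' Non-positive experiences (free moves, wall bumps, absent rewards) are
#' shared into every context's base model except where a context believes
#' reward, so stored contexts differ only in their reward structure. The
#' buffer is cleared whenever the active context changes.
#'
#' @param maze a [grid_maze()].
#' @param m history buffer length (default 10).
#' @param new_context_threshold minimum explanation probability a stored
#'   context must offer before it can absorb a reward-prediction violation
#'   (default 0.5). Explanations are evidence-based — a context that has
#'   itself experienced the reward at the place scores 1, others 0 — so any
#'   value in (0, 1] behaves identically; values above 1 force a new
#'   context on every violation.
#' @param temperature softmax temperature over log-likelihoods (default 1).
#' @param ... agent configuration passed to [nav_agent()] for every context
#'   (e.g. `budgets`, `epsilon`).
#' @return An object of class `context_agent`.
#' @export
context_agent <- function(maze, m = 10, new_context_threshold = 0.5,
                          temperature = 1, ...) {
  template <- nav_agent(maze, reward_dist = TRUE, ...)
  cfg <- c(template$config,
           list(history_m = as.integer(m),
                new_context_threshold = new_context_threshold,
                temperature = temperature))
  ptr <- new(ContextBank, maze_to_cpp(maze), template$specs, cfg)
  structure(list2env(list(ptr = ptr, maze = maze, specs = template$specs,
                          config = cfg)),
            class = "context_agent")
}

#' @export
print.context_agent <- function(x, ...) {
  cat(sprintf("<context_agent> %d context(s), active %d, m = %d\n",
              n_contexts(x), active_context(x), x$config$history_m))
  invisible(x)
}

#' Context bank accessors
#' @param agent a `context_agent`.
#' @return `n_contexts()`: number of stored contexts; `active_context()`:
#'   1-based index of the context in use.
#' @export
n_contexts <- function(agent) agent$ptr$nContexts()

#' @rdname n_contexts
#' @export
active_context <- function(agent) agent$ptr$activeContext() + 1L

#' Seed a stored context's base model with an experience
#'
#' Test and set-up helper: records `(s, a, sp, r)` directly in context `k`'s
#' base world model (no sweeping, no history update).
#'
#' @param agent a `context_agent`.
#' @param k context index (1-based).
#' @param s,sp base state ids.
#' @param a action 1..4 or name.
#' @param r reward.
#' @param terminal whether `sp` is reward-absorbing.
#' @export
observe_context <- function(agent, k, s, a, sp, r, terminal = FALSE) {
  agent$ptr$observeAs(k - 1L, s - 1L, action_code(a) - 1L, sp - 1L, r,
                      isTRUE(terminal))
  invisible(agent)
}

#' Append an experience to the shared history buffer
#' @inheritParams observe_context
#' @export
push_experience <- function(agent, s, a, sp, r) {
  agent$ptr$pushExperience(s - 1L, action_code(a) - 1L, sp - 1L, r)
  invisible(agent)
}

#' Geometric-mean history likelihood of every context
#'
#' `g_k = P_k(H)^(1/|H|)` for the current buffer; `1` for all contexts when
#' the buffer is empty.
#'
#' @param agent a `context_agent`.
#' @return numeric vector, one entry per context.
#' @export
history_g <- function(agent) agent$ptr$historyG()

#' Evaluate the context bank now
#'
#' Applies the routine switching rule to the current buffer: when the active
#' context is no longer the best explanation of the history, a replacement
#' is drawn from a softmax over the history log-likelihoods. Consumes R
#' random numbers.
#'
#' @param agent a `context_agent`.
#' @return list with `changed` and `active` (1-based).
#' @export
evaluate_contexts <- function(agent) {
  r <- agent$ptr$evaluateNow()
  list(changed = r$changed, active = r$active + 1L)
}

#' Reward-expectation surprise check
#'
#' `TRUE` when context `k`'s base model holds a reward expectation on the
#' observed transition that the experienced reward violates: positive
#' expectation with a non-positive reward (a disappointment) or
#' non-positive expectation with a positive reward (a recognition event).
#' Unknown transitions are never
#' surprising.
#'
#' @inheritParams observe_context
#' @return logical.
#' @export
surprise_check <- function(agent, k, s, a, sp, r) {
  agent$ptr$surprise(k - 1L, s - 1L, action_code(a) - 1L, sp - 1L, r)
}

#' Per-context reward probability of an experience's outcome
#'
#' `P_k(r | arriving in sp)` for every stored context, aggregated over all
#' recorded entries into `sp` — the quantity that decides whether some
#' stored context "explains" a reward-prediction violation.
#'
#' @inheritParams observe_context
#' @return numeric vector, one entry per context.
#' @export
experience_explainers <- function(agent, s, a, sp, r) {
  agent$ptr$explainers(s - 1L, action_code(a) - 1L, sp - 1L, r)
}
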