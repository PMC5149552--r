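#' Construct a lesioned variant of a hierarchical agent
#'
#' Simulated hippocampal lesions remove parts of the abstraction stack:
#'
#' * `"vH"` (ventral): only the base level survives — a conventional
#'   single-level model-based agent. It receives the intact agent's total
#'   update budget so comparisons hold the per-step budget fixed.
#' * `"dH"` (dorsal): only the highest informative level (the topmost level
#'   with more than one macro-state) survives as a model-based goal-setter,
#'   while the base level is replaced by a model-free Q-learner. Actions are
#'   chosen epsilon-greedily on the composite score
#'   `Q_free(s, a) + Q_top(macro(s), a)`.
#' * `"none"`: a fresh intact agent with the same configuration.
#'
#' Lesions are congenital: the returned agent is untrained.
#'
#' @param agent an intact `nav_agent` (its maze and configuration are
#'   reused).
#' @param kind one of `"none"`, `"vH"`, `"dH"`.
#' @return a new `nav_agent`.
#' @export
apply_lesion <- function(agent, kind = c("none", "vH", "dH")) {
  kind <- match.arg(kind)
  maze <- agent$maze
  cfg <- agent$config
  specs <- agent$specs
  total_budget <- sum(vapply(specs, function(l) l$budget, 0L))
  if (kind == "none") {
    out <- new_nav_agent(maze, specs, cfg, kind)
  } else if (kind == "vH") {
    base <- specs[[1]]
    base$budget <- as.integer(total_budget)
    out <- new_nav_agent(maze, list(base), cfg, kind)
  } else {
    sizes <- vapply(specs, function(l) l$rows * l$cols, 0)
    top <- max(which(sizes > 1))
    if (top < 2) stop("dH lesion needs a level above the base", call. = FALSE)
    base <- specs[[1]]
    base$model_based <- FALSE
    top_spec <- specs[[top]]
    top_spec$budget <- as.integer(total_budget)
    # the dH agent cannot refine plans, so exploratory optimism at the
    # surviving macro level has no planner to serve and only injects an
    # arbitrary directional bias into the composite score; before reward
    # discovery its behaviour should be uninformed (random)
    cfg$optimism <- 0
    # compose the base -> top map across the removed intermediate levels
    hier <- build_hierarchy(maze)
    up <- seq_len(hier[[1]]$n)
    for (k in 2:top) up <- hier[[k]]$up[up]
    top_spec$up <- up - 1L
    out <- new_nav_agent(maze, list(base, top_spec), cfg, kind)
  }
  out
}
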