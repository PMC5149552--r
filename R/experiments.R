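#' Experiment drivers
#'
#' Reproducible drivers for the four simulation studies: lesion comparison,
#' boundary adaptation, probabilistic-reward contexts, and scaling. A single
#' master seed spawns an independent seed for every (group, repetition)
#' pair, so each group sees an independent random stream and the full record
#' table is a deterministic function of `(configuration, seed)`.
#'
#' @name experiments
NULL

# independent per-(group, rep) seeds derived from one master seed
spawn_seeds <- function(seed, groups, reps) {
  set.seed(seed)
  m <- matrix(sample.int(.Machine$integer.max - 1L, length(groups) * reps),
              nrow = length(groups), dimnames = list(groups, NULL))
  m
}

#' Lesion experiment: intact vs ventral vs dorsal lesions
#'
#' Runs the intact hierarchical agent and its vH- and dH-lesioned variants
#' (see [apply_lesion()]) on an open arena for `trials` trials per
#' repetition, recording steps to goal and cumulative model accesses.
#'
#' @param reps repetitions per group (56 in the full study).
#' @param trials trials per repetition (default 30).
#' @param maze arena; default the 16 x 48 open arena.
#' @param lesions subset of `c("none", "vH", "dH")`.
#' @param budget_per_level per-level sweep budget of the intact agent
#'   (default 20; lesioned variants inherit the total).
#' @param seed master seed.
#' @return tibble of per-trial records with columns `group`, `rep`, `trial`,
#'   `steps`, `accesses`, `reached`, `seed`.
#' @export
run_lesion_experiment <- function(reps = 8, trials = 30, maze = NULL,
                                  lesions = c("none", "vH", "dH"),
                                  budget_per_level = 20, seed = 1) {
  if (is.null(maze)) maze <- make_open_arena(16, 48)
  seeds <- spawn_seeds(seed, lesions, reps)
  out <- list()
  for (g in lesions) {
    for (i in seq_len(reps)) {
      set.seed(seeds[g, i])
      intact <- nav_agent(maze, budgets = budget_per_level)
      ag <- apply_lesion(intact, g)
      rec <- run_trials(ag, trials)
      rec$group <- g
      rec$rep <- i
      rec$seed <- seeds[g, i]
      out[[length(out) + 1L]] <- rec
    }
  }
  do.call(rbind, out)[, c("group", "rep", "trial", "steps", "accesses",
                          "reached", "seed")]
}

#' Boundary-adaptation experiment
#'
#' Each agent learns the open 16 x 48 arena for `trials_open` trials; then
#' internal boundaries (one of the five adaptation mazes) are added and the
#' agent must adapt for `trials_maze` more trials. Hierarchical (six levels,
#' 20 updates/step each) and conventional (one level, 120 updates/step)
#' agents are compared at equal total budgets.
#'
#' @param variant adaptation maze, `"A"`..`"E"`.
#' @param reps repetitions per agent group.
#' @param trials_open,trials_maze trials before/after the change.
#' @param seed master seed.
#' @return tibble with columns `group`, `rep`, `trial`, `phase`
#'   (`"open"`/`"maze"`), `steps`, `accesses`, `reached`, `seed`.
#' @export
run_adaptation_experiment <- function(variant, reps = 8, trials_open = 10,
                                      trials_maze = 10, seed = 1) {
  groups <- c("hierarchical", "conventional")
  seeds <- spawn_seeds(seed, groups, reps)
  arena <- make_open_arena(16, 48)
  walled <- make_adaptation_maze(variant)
  out <- list()
  for (g in groups) {
    for (i in seq_len(reps)) {
      set.seed(seeds[g, i])
      ag <- if (g == "hierarchical") nav_agent(arena, budgets = 20)
            else conventional_agent(arena, budget = 120)
      r1 <- run_trials(ag, trials_open)
      r1$phase <- "open"
      set_maze(ag, walled)
      r2 <- run_trials(ag, trials_maze)
      r2$phase <- "maze"
      r2$trial <- r2$trial + trials_open
      rec <- rbind(r1, r2)
      rec$group <- g
      rec$rep <- i
      rec$seed <- seeds[g, i]
      out[[length(out) + 1L]] <- rec
    }
  }
  res <- do.call(rbind, out)
  res$variant <- variant
  res[, c("group", "variant", "rep", "trial", "phase", "steps", "accesses",
          "reached", "seed")]
}

#' Probabilistic-reward context experiment
#'
#' On the 7 x 7 four-goal arena the reward is placed uniformly at random at
#' one of the four corner sites each trial (500-step cap). The
#' context-enabled hierarchical agent is compared with a conventional
#' single-level agent facing the same site sequence distribution.
#'
#' @param reps repetitions per group.
#' @param trials trials per repetition (default 40).
#' @param m history buffer length (default 10).
#' @param seed master seed.
#' @return tibble with columns `group`, `rep`, `trial`, `site`, `steps`,
#'   `accesses`, `reached`, `context`, `n_contexts`, `seed` (`context`
#'   columns are `NA` for the conventional agent).
#' @export
run_context_experiment <- function(reps = 8, trials = 40, m = 10, seed = 1) {
  groups <- c("context", "conventional")
  seeds <- spawn_seeds(seed, groups, reps)
  maze <- make_four_goal_maze()
  sites <- attr(maze, "reward_sites")
  site_ids <- cell_id(maze, sites)
  out <- list()
  for (g in groups) {
    for (i in seq_len(reps)) {
      set.seed(seeds[g, i])
      site_seq <- sample.int(4L, trials, replace = TRUE)
      ag <- if (g == "context") context_agent(maze, m = m, budgets = 20)
            else conventional_agent(maze, budget = 120)
      rec <- run_trials(ag, trials, goals = site_ids[site_seq])
      if (!"context" %in% names(rec)) {
        rec$context <- NA_integer_
        rec$n_contexts <- NA_integer_
      }
      rec$site <- site_seq
      rec$group <- g
      rec$rep <- i
      rec$seed <- seeds[g, i]
      out[[length(out) + 1L]] <- rec
    }
  }
  do.call(rbind, out)[, c("group", "rep", "trial", "site", "steps",
                          "accesses", "reached", "context", "n_contexts",
                          "seed")]
}

#' Scaling experiment
#'
#' Scales the 16 x 48 arena by the given factors and runs both agents for
#' `trials` trials at equal total update budgets, recording steps and model
#' accesses. A repetition counts as failed when the goal is not reached in
#' any trial.
#'
#' @param factors scale factors (must yield integer dimensions).
#' @param reps repetitions per (group, factor).
#' @param trials trials per repetition (default 3).
#' @param seed master seed.
#' @return tibble with columns `group`, `factor`, `states`, `rep`, `trial`,
#'   `steps`, `accesses`, `reached`, `seed`.
#' @export
run_scaling_experiment <- function(factors = c(1, 1.5, 2), reps = 5,
                                   trials = 3, seed = 1) {
  groups <- c("hierarchical", "conventional")
  seeds <- spawn_seeds(seed, groups, reps * length(factors))
  out <- list()
  for (g in groups) {
    k <- 0L
    for (f in factors) {
      maze <- scale_arena(16, 48, f)
      for (i in seq_len(reps)) {
        k <- k + 1L
        set.seed(seeds[g, k])
        ag <- if (g == "hierarchical") nav_agent(maze, budgets = 20)
              else conventional_agent(maze, budget = 120)
        rec <- run_trials(ag, trials)
        rec$group <- g
        rec$factor <- f
        rec$states <- maze$rows * maze$cols
        rec$rep <- i
        rec$seed <- seeds[g, k]
        out[[length(out) + 1L]] <- rec
      }
    }
  }
  do.call(rbind, out)[, c("group", "factor", "states", "rep", "trial",
                          "steps", "accesses", "reached", "seed")]
}

#' Summarise per-trial records
#'
#' Per-trial mean and 2.5/97.5 percentile band of a record column, within
#' every combination of the grouping columns present (`group`, `variant`,
#' `factor`, `phase`, `trial`).
#'
#' @param records a record tibble from one of the experiment drivers.
#' @param value column to summarise (default `"steps"`).
#' @return tibble with `mean`, `p2.5`, `p97.5` per group/trial.
#' @export
summarize_trials <- function(records, value = "steps") {
  if (NROW(records) == 0L) stop("no records to summarise", call. = FALSE)
  keys <- intersect(c("group", "variant", "factor", "phase", "trial"),
                    names(records))
  f <- stats::as.formula(paste(value, "~", paste(keys, collapse = " + ")))
  agg <- aggregate(f, data = records, FUN = function(x) {
    c(mean = mean(x), quantile(x, c(0.025, 0.975), names = FALSE))
  })
  stats <- agg[[value]]
  agg[[value]] <- NULL
  agg$mean <- stats[, 1]
  agg$p2.5 <- stats[, 2]
  agg$p97.5 <- stats[, 3]
  tibble::as_tibble(agg[order(agg[[keys[1]]]), ])
}

#' Rank-sum comparison of two agent groups
#'
#' Wilcoxon rank-sum test on per-repetition totals of a record column,
#' optionally restricted (e.g. to the post-change phase).
#'
#' @param records a record tibble with a `group` column.
#' @param groups the two group labels to compare.
#' @param value column to total per repetition (default `"steps"`).
#' @param subset optional logical vector selecting records first.
#' @param fun per-repetition aggregator (default `sum`; use `max` for
#'   cumulative columns such as `accesses`).
#' @return the `htest` object from [stats::wilcox.test()].
#' @export
rank_sum_test <- function(records, groups, value = "steps", subset = NULL,
                          fun = sum) {
  if (!is.null(subset)) records <- records[subset, ]
  tot <- aggregate(records[[value]],
                   by = list(group = records$group, rep = records$rep), FUN = fun)
  x <- tot$x[tot$group == groups[1]]
  y <- tot$x[tot$group == groups[2]]
  wilcox.test(x, y, exact = FALSE)
}
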