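test_that("history likelihood is the product of experience probabilities", {
  maze <- make_open_arena(4, 6)
  ca <- context_agent(maze)
  ag <- list(ptr = ca$ptr, maze = maze)  # likelihoods live on the bank's agent
  # craft one experience of probability exactly 0.4 and one of 0.5
  observe_context(ca, 1, 8, "right", 9, 0)
  observe_context(ca, 1, 8, "right", 8, 0)
  observe_context(ca, 1, 8, "right", 8, 0)
  h2 <- data.frame(s = c(8, 14), a = c(4, 3), sp = c(9, 13), r = c(0, 0))
  bank_ag <- nav_agent(maze, reward_dist = TRUE)
  model_observe(bank_ag, 1, 8, "right", 9, 0)
  model_observe(bank_ag, 1, 8, "right", 8, 0)
  model_observe(bank_ag, 1, 8, "right", 8, 0)
  expect_identical(experience_prob(bank_ag, 8, "right", 9, 0), 0.4)
  expect_identical(experience_prob(bank_ag, 14, "left", 13, 0), 0.5)
  expect_identical(history_likelihood(bank_ag, h2), 0.2)
  # empty history: probability one
  expect_identical(history_likelihood(bank_ag, h2[0, ]), 1)
  # appending an experience multiplies the likelihood by its probability
  h3 <- rbind(h2, data.frame(s = 8, a = 4, sp = 9, r = 0))
  expect_equal(history_likelihood(bank_ag, h3),
               history_likelihood(bank_ag, h2) *
                 experience_prob(bank_ag, 8, "right", 9, 0))
})

test_that("surprise fires only on reward-prediction violations", {
  maze <- make_four_goal_maze()
  ca <- context_agent(maze)
  site <- cell_id(maze, c(1, 1))
  adj <- cell_id(maze, c(2, 1))
  # learned goal cell visited, no reward delivered -> surprising
  observe_context(ca, 1, adj, "up", site, 100, terminal = TRUE)
  expect_true(surprise_check(ca, 1, adj, "up", site, 0))
  # expected 0, got 0 -> not surprising
  observe_context(ca, 1, 10, "right", 11, 0)
  expect_false(surprise_check(ca, 1, 10, "right", 11, 0))
  # expected -1, got -1 -> negative expectations don't trigger
  observe_context(ca, 1, 8, "up", 8, -1)
  expect_false(surprise_check(ca, 1, 8, "up", 8, -1))
  # unknown transition -> never surprising
  expect_false(surprise_check(ca, 1, 30, "down", 37, 0))
  # reward where none was expected -> recognition surprise
  expect_true(surprise_check(ca, 1, 10, "right", 11, 100))
})

test_that("the trained context explains its environment best", {
  maze <- make_four_goal_maze()
  sites <- cell_id(maze, attr(maze, "reward_sites"))
  set.seed(4)
  ca <- context_agent(maze, budgets = 20)
  # run enough trials on alternating sites that several contexts exist
  set.seed(4)
  seq1 <- rep(c(1, 2), each = 4)
  invisible(run_trials(ca, length(seq1), goals = sites[seq1]))
  expect_gte(n_contexts(ca), 2)
  # per-context reward explanation at a known site separates contexts
  p1 <- experience_explainers(ca, sites[1] + 1, "left", sites[1], 100)
  expect_gte(max(p1), 0.5)
  expect_gt(max(p1), min(p1))
})

test_that("the bank grows on unexplained reward changes and converges to four contexts", {
  maze <- make_four_goal_maze()
  sites <- cell_id(maze, attr(maze, "reward_sites"))
  set.seed(42)
  site_seq <- sample.int(4, 40, replace = TRUE)
  set.seed(42)
  ca <- context_agent(maze, budgets = 20)
  r <- run_trials(ca, 40, goals = sites[site_seq])
  expect_gte(tail(r$n_contexts, 1), 4 - 1)
  expect_lte(tail(r$n_contexts, 1), 4 + 2)
  # contexts stop growing once all sites are represented
  expect_equal(tail(r$n_contexts, 1), r$n_contexts[30])
})

test_that("context switching is reproducible under a seed", {
  maze <- make_four_goal_maze()
  sites <- cell_id(maze, attr(maze, "reward_sites"))
  run_once <- function() {
    set.seed(17)
    site_seq <- sample.int(4, 15, replace = TRUE)
    ca <- context_agent(maze, budgets = 20)
    run_trials(ca, 15, goals = sites[site_seq])
  }
  expect_identical(run_once(), run_once())
})

test_that("routine evaluation switches toward the better-explaining context", {
  maze <- make_four_goal_maze()
  ca <- context_agent(maze, budgets = 20)
  sites <- cell_id(maze, attr(maze, "reward_sites"))
  set.seed(9)
  invisible(run_trials(ca, 8, goals = rep(sites[1:2], 4)))
  k <- n_contexts(ca)
  expect_gte(k, 2)
  # feed a decisive window — repeated reward at site 1 — and evaluate: the
  # context that explains it must end up active, and its likelihood must be
  # at least that of the context it replaced
  adj <- sites[1] + 1L
  for (i in seq_len(6)) push_experience(ca, adj, "left", sites[1], 100)
  g_before <- history_g(ca)
  before <- active_context(ca)
  set.seed(1)
  ev <- evaluate_contexts(ca)
  expect_equal(g_before[ev$active], max(g_before), tolerance = 1e-9)
  expect_gte(g_before[ev$active], g_before[before] - 1e-12)
})
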