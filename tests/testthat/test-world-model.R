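# the world-model surface is exercised through a single-level agent on a
# small open arena; level-state ids equal maze cell ids there
fresh <- function(rows = 4, cols = 6, ...) {
  conventional_agent(make_open_arena(rows, cols), ...)
}

test_that("observe keeps an exact running mean of rewards", {
  ag <- fresh()
  # interior cell 8 = (2,2); action right -> 9
  model_observe(ag, 1, 8, "right", 9, 100)
  wm <- world_model(ag)
  expect_equal(wm$rmean[wm$s == 8 & wm$a == 4], 100)
  model_observe(ag, 1, 8, "right", 9, 0)
  wm <- world_model(ag)
  expect_equal(wm$rmean[wm$s == 8 & wm$a == 4], 50)
  expect_equal(wm$n[wm$s == 8 & wm$a == 4], 2)
  for (i in 1:3) model_observe(ag, 1, 14, "left", 13, -1)
  wm <- world_model(ag)
  expect_equal(wm$rmean[wm$s == 14 & wm$a == 3], -1)
  expect_equal(wm$n[wm$s == 14 & wm$a == 3], 3)
})

test_that("running mean equals the arithmetic mean of any reward sequence", {
  set.seed(7)
  for (rep in 1:10) {
    ag <- fresh(reward_dist = TRUE)
    rs <- sample(c(-1, 0, 100), sample(1:12, 1), replace = TRUE)
    for (r in rs) model_observe(ag, 1, 8, "right", 9, r)
    wm <- world_model(ag)
    expect_equal(wm$rmean[wm$s == 8 & wm$a == 4], mean(rs))
    # oracle: recompute mean from the stored histogram
    h <- reward_histogram(ag)
    h <- h[h$s == 8 & h$a == 4, ]
    expect_equal(sum(h$reward * h$count) / sum(h$count), mean(rs))
    expect_equal(sum(h$count), length(rs))
  }
})

test_that("smoothed transition probabilities follow the prior-count formula", {
  ag <- fresh()
  # untried pair: uniform over the two candidates (neighbour, self)
  expect_equal(transition_prob(ag, 1, 8, "right", 9), 0.5)
  expect_equal(transition_prob(ag, 1, 8, "right", 8), 0.5)
  # one observation of the neighbour: (1+1)/(1+0+2)
  model_observe(ag, 1, 8, "right", 9, 0)
  expect_equal(transition_prob(ag, 1, 8, "right", 9), 2 / 3)
  # the prior-count arithmetic of the formula itself, over a 4-candidate
  # set with one observation: (1+1)/(1+4) = 0.4 exactly
  counts <- c(1, 0, 0, 0)
  expect_identical((counts[1] + 1) / sum(counts + 1), 0.4)
  expect_equal(transition_prob(ag, 1, 8, "right", 9),
               (1 + 1) / sum(c(1, 0) + 1))
  # outside the candidate set: zero
  expect_equal(transition_prob(ag, 1, 8, "right", 11), 0)
})

test_that("transition probabilities normalise and converge monotonically", {
  ag <- fresh()
  p_hist <- numeric(0)
  for (n in c(1, 10, 100, 1000)) {
    for (i in seq_len(n)) model_observe(ag, 1, 8, "right", 9, 0)
    p <- transition_prob(ag, 1, 8, "right", 9)
    p_hist <- c(p_hist, p)
  }
  expect_true(all(diff(p_hist) > 0))
  expect_gt(tail(p_hist, 1), 0.999)
  # normalisation over the candidate set, many random table states
  set.seed(11)
  for (i in 1:50) {
    s <- sample(24, 1)
    a <- sample(4, 1)
    tot <- transition_prob(ag, 1, s, a, s)
    st <- maze_step(make_open_arena(4, 6),
                    cell_rc(make_open_arena(4, 6), s), a)
    nb <- cell_id(make_open_arena(4, 6), st$next_state)
    if (nb != s) tot <- tot + transition_prob(ag, 1, s, a, nb)
    expect_equal(tot, 1, tolerance = 1e-12)
  }
})

test_that("counts commute: observation order does not change T or the mean", {
  obs <- list(c(9, 0), c(8, 0), c(9, 100), c(9, 0), c(8, -1))
  run <- function(order) {
    ag <- fresh(reward_dist = TRUE)
    for (i in order) model_observe(ag, 1, 8, "right", obs[[i]][1], obs[[i]][2])
    list(wm = world_model(ag), h = reward_histogram(ag))
  }
  a <- run(1:5)
  b <- run(c(4, 2, 5, 1, 3))
  expect_equal(a$wm[order(a$wm$s, a$wm$a, a$wm$sp), ],
               b$wm[order(b$wm$s, b$wm$a, b$wm$sp), ])
  expect_equal(a$h[order(a$h$sp, a$h$reward), ]$count,
               b$h[order(b$h$sp, b$h$reward), ]$count)
})

test_that("experience probability multiplies transition and reward factors", {
  ag <- fresh(reward_dist = TRUE)
  # craft P(transition) = 2/5 with a single observed reward value, so the
  # reward factor is exactly 1 and P(e) = 0.4
  model_observe(ag, 1, 8, "right", 9, 0)
  model_observe(ag, 1, 8, "right", 8, 0)
  model_observe(ag, 1, 8, "right", 8, 0)
  expect_identical(experience_prob(ag, 8, "right", 9, 0), 0.4)
  # fresh pair elsewhere: uniform transition prior, reward factor 1
  expect_identical(experience_prob(ag, 14, "left", 13, 0), 0.5)
  # an impossible reward for a well-observed transition is far less likely
  # than the transition alone
  for (i in 1:20) model_observe(ag, 1, 20, "right", 21, 0)
  p_seen <- experience_prob(ag, 20, "right", 21, 0)
  p_unseen <- experience_prob(ag, 20, "right", 21, 100)
  expect_lt(p_unseen, transition_prob(ag, 1, 20, "right", 21) / 5)
  expect_gt(p_seen, 0.8)
})

test_that("predicted successor follows counts with fixed tie-breaking", {
  ag <- fresh()
  for (i in 1:3) model_observe(ag, 1, 8, "right", 9, 0)
  model_observe(ag, 1, 8, "right", 8, -1)
  expect_equal(predicted_successor(ag, 1, 8, "right"), 9)
  # untried: geometric fallback
  expect_equal(predicted_successor(ag, 1, 14, "down"), 20)
  # tie: lower state id
  ag2 <- fresh()
  model_observe(ag2, 1, 8, "right", 9, 0)
  model_observe(ag2, 1, 8, "right", 8, -1)
  expect_equal(predicted_successor(ag2, 1, 8, "right"), 8)
})

test_that("world models serialize to text and round-trip", {
  ag <- fresh()
  set.seed(3)
  maze <- make_open_arena(4, 6)
  invisible(run_trials(ag, 2))
  path <- tempfile(fileext = ".tsv")
  write_world_model(ag, path)
  wm <- read_world_model(path)
  ag2 <- fresh()
  load_world_model(ag2, wm)
  expect_equal(world_model(ag2), world_model(ag))
  # probabilities computed from the restored model agree
  expect_equal(transition_prob(ag2, 1, 8, "right", 9),
               transition_prob(ag, 1, 8, "right", 9))
  unlink(path)
})
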