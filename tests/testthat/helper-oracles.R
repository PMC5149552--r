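# independent oracles and small builders used across the suite

# breadth-first shortest path length (number of states on the path) between
# two cells of a maze, or NA when unreachable
bfs_path_states <- function(maze, from, to) {
  n <- maze$rows * maze$cols
  free <- !as.vector(t(maze$walls))
  dist <- rep(NA_integer_, n)
  src <- cell_id(maze, from)
  dst <- cell_id(maze, to)
  dist[src] <- 1L
  q <- src
  while (length(q)) {
    s <- q[1]
    q <- q[-1]
    if (s == dst) return(dist[s])
    r <- (s - 1L) %/% maze$cols
    c <- (s - 1L) %% maze$cols
    for (a in 1:4) {
      nr <- r + c(-1L, 1L, 0L, 0L)[a]
      nc <- c + c(0L, 0L, -1L, 1L)[a]
      if (nr < 0L || nr >= maze$rows || nc < 0L || nc >= maze$cols) next
      id <- nr * maze$cols + nc + 1L
      if (free[id] && is.na(dist[id])) {
        dist[id] <- dist[s] + 1L
        q <- c(q, id)
      }
    }
  }
  NA_integer_
}

# synchronous value iteration on the agent's learned (smoothed) base model:
# the same MDP prioritized sweeping solves. States without any observation
# stay frozen at the optimistic initial value, terminal states contribute no
# continuation and are never updated.
vi_oracle <- function(agent, gamma, optimism = 1, tol = 1e-12, iter = 10000) {
  maze <- agent$maze
  n <- maze$rows * maze$cols
  wm <- world_model(agent, 1)
  Tc <- array(0L, c(n, 4, 2))  # slot 1 geometric succ, slot 2 self
  Rm <- array(0, c(n, 4, 2))
  term <- rep(FALSE, n)
  gs <- function(s, a) {
    r <- (s - 1L) %/% maze$cols + c(-1L, 1L, 0L, 0L)[a]
    c <- (s - 1L) %% maze$cols + c(0L, 0L, -1L, 1L)[a]
    if (r < 0L || r >= maze$rows || c < 0L || c >= maze$cols) return(NA_integer_)
    r * maze$cols + c + 1L
  }
  for (i in seq_len(nrow(wm))) {
    slot <- if (wm$sp[i] == wm$s[i]) 2L else 1L
    Tc[wm$s[i], wm$a[i], slot] <- wm$n[i]
    Rm[wm$s[i], wm$a[i], slot] <- wm$rmean[i]
    if (wm$terminal[i]) term[wm$sp[i]] <- TRUE
  }
  observed <- apply(Tc, 1, sum) > 0
  Q <- matrix(optimism, n, 4)
  Q[term, ] <- 0
  maxq <- function(Q, s) if (term[s]) 0 else max(Q[s, ])
  for (it in seq_len(iter)) {
    Qn <- Q
    for (s in which(observed & !term)) {
      for (a in 1:4) {
        g <- gs(s, a)
        v <- 0
        if (!is.na(g) && g != s) {
          den <- (Tc[s, a, 1] + 1) + (Tc[s, a, 2] + 1)
          v <- (Tc[s, a, 1] + 1) / den * (Rm[s, a, 1] + gamma * maxq(Q, g)) +
            (Tc[s, a, 2] + 1) / den * (Rm[s, a, 2] + gamma * maxq(Q, s))
        } else {
          v <- Rm[s, a, 2] + gamma * maxq(Q, s)
        }
        Qn[s, a] <- v
      }
    }
    d <- max(abs(Qn - Q))
    Q <- Qn
    if (d < tol) break
  }
  Q
}

# random small maze (at most max_cells cells) with a guaranteed path
random_small_maze <- function(max_cells = 25, p_wall = 0.15) {
  repeat {
    rows <- sample(2:5, 1)
    cols <- sample(2:5, 1)
    if (rows * cols > max_cells) next
    walls <- matrix(runif(rows * cols) < p_wall, rows, cols)
    free <- which(!walls, arr.ind = TRUE)
    if (nrow(free) < 3) next
    pick <- free[sample(nrow(free), 2), , drop = FALSE]
    m <- tryCatch(
      grid_maze(rows, cols, walls, pick[1, ], pick[2, ], step_cap = 500),
      error = function(e) NULL)
    if (is.null(m)) next
    if (maze_connected(m)) return(m)
  }
}

# expose every transition of a maze to a single-level agent, several passes,
# so the learned model fully covers the grid
teach_maze <- function(agent, maze, passes = 2) {
  for (p in seq_len(passes)) {
    for (r in seq_len(maze$rows)) {
      for (c in seq_len(maze$cols)) {
        if (maze$walls[r, c]) next
        for (a in 1:4) {
          st <- maze_step(maze, c(r, c), a)
          agent_observe(agent, c(r, c), a, st$next_state, st$reward,
                        st$goal_reached)
        }
      }
    }
  }
  invisible(agent)
}

# drive one trial from R via the exposed primitives (same code path as the
# C++ loop, but stepping through the public API)
drive_trial <- function(agent, maze, cap = 500) {
  s <- maze$start
  path <- integer(0)
  for (i in seq_len(cap)) {
    act <- agent_act(agent, s)
    st <- maze_step(maze, s, act$action)
    agent_observe(agent, s, act$action, st$next_state, st$reward,
                  st$goal_reached)
    path <- c(path, cell_id(maze, s))
    if (st$goal_reached) {
      reset_episode(agent)
      return(list(steps = i, reached = TRUE, path = path))
    }
    s <- st$next_state
  }
  reset_episode(agent)
  list(steps = cap, reached = FALSE, path = path)
}
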