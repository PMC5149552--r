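#' Construct a grid maze
#'
#' A discrete rectangular arena in which an agent moves between cells with
#' the four compass actions. Walls block movement; attempting to enter a wall
#' or leave the grid keeps the agent in place and costs `wall_penalty`.
#' Entering the goal cell delivers `goal_reward` and ends the trial (the
#' caller relocates the agent to `start`).
#'
#' Cells are addressed as `c(row, col)`, 1-based, row 1 at the top. State ids
#' used by the modelling functions are row-major: `id = (row-1)*cols + col`
#' (see [cell_id()] and [cell_rc()]).
#'
#' @param rows,cols grid dimensions, both at least 2.
#' @param walls logical `rows x cols` matrix, `TRUE` for blocked cells, or
#'   `NULL` for an open arena.
#' @param start,goal `c(row, col)` cells; must be free, in bounds, distinct.
#' @param goal_reward reward delivered on reaching the goal (default 100).
#' @param wall_penalty reward for bumping a wall or the boundary (default -1).
#' @param step_cap maximum steps per trial before the agent is relocated.
#' @return An object of class `grid_maze`.
#' @export
grid_maze <- function(rows, cols, walls = NULL, start, goal,
                      goal_reward = 100, wall_penalty = -1, step_cap = 5000) {
  rows <- as.integer(rows)
  cols <- as.integer(cols)
  if (rows < 2L || cols < 2L) stop("maze must be at least 2 x 2", call. = FALSE)
  if (is.null(walls)) walls <- matrix(FALSE, rows, cols)
  walls <- matrix(as.logical(walls), rows, cols)
  start <- as.integer(start)
  goal <- as.integer(goal)
  chk <- function(cell, what) {
    if (length(cell) != 2L || any(cell < 1L) || cell[1] > rows || cell[2] > cols)
      stop(what, " out of bounds", call. = FALSE)
    if (walls[cell[1], cell[2]]) stop(what, " lies inside a wall", call. = FALSE)
  }
  chk(start, "start")
  chk(goal, "goal")
  if (all(start == goal)) stop("start and goal must differ", call. = FALSE)
  structure(
    list(rows = rows, cols = cols, walls = walls, start = start, goal = goal,
         goal_reward = goal_reward, wall_penalty = wall_penalty,
         step_cap = as.integer(step_cap)),
    class = "grid_maze")
}

#' @export
print.grid_maze <- function(x, ...) {
  cat(sprintf("<grid_maze> %d x %d (%d free states), start (%d,%d), goal (%d,%d), cap %d\n",
              x$rows, x$cols, sum(!x$walls), x$start[1], x$start[2],
              x$goal[1], x$goal[2], x$step_cap))
  invisible(x)
}

#' Convert between cell coordinates and state ids
#'
#' State ids are 1-based and row-major on the maze grid.
#'
#' @param maze a [grid_maze()] (only `cols` is used).
#' @param rc a `c(row, col)` cell or a 2-column matrix of cells.
#' @return `cell_id()`: integer id(s); `cell_rc()`: a cell or matrix of cells.
#' @export
cell_id <- function(maze, rc) {
  if (is.matrix(rc)) return((rc[, 1] - 1L) * maze$cols + rc[, 2])
  (rc[1] - 1L) * maze$cols + rc[2]
}

#' @rdname cell_id
#' @param id state id(s) as returned by `cell_id()`.
#' @export
cell_rc <- function(maze, id) {
  r <- (id - 1L) %/% maze$cols + 1L
  c <- (id - 1L) %% maze$cols + 1L
  if (length(id) > 1L) cbind(row = r, col = c) else c(r, c)
}

#' Take one environment step
#'
#' Deterministic transition function of the maze. Moving into a wall or off
#' the grid leaves the agent in place with `wall_penalty`; moving onto the
#' goal yields `goal_reward` and flags the end of the trial; any other move
#' is free and rewards 0.
#'
#' @param maze a [grid_maze()].
#' @param state `c(row, col)`; must be a free in-bounds cell.
#' @param action 1..4 or one of `"up"`, `"down"`, `"left"`, `"right"`.
#' @return list with `next_state` (`c(row, col)`), `reward`, `goal_reached`.
#' @export
maze_step <- function(maze, state, action) {
  state <- as.integer(state)
  if (any(state < 1L) || state[1] > maze$rows || state[2] > maze$cols)
    stop("state out of bounds", call. = FALSE)
  if (maze$walls[state[1], state[2]])
    stop("state lies inside a wall", call. = FALSE)
  a <- action_code(action)
  dr <- c(-1L, 1L, 0L, 0L)[a]
  dc <- c(0L, 0L, -1L, 1L)[a]
  tgt <- state + c(dr, dc)
  out_of_grid <- tgt[1] < 1L || tgt[1] > maze$rows || tgt[2] < 1L || tgt[2] > maze$cols
  if (out_of_grid || maze$walls[tgt[1], tgt[2]])
    return(list(next_state = state, reward = maze$wall_penalty, goal_reached = FALSE))
  if (all(tgt == maze$goal))
    return(list(next_state = tgt, reward = maze$goal_reward, goal_reached = TRUE))
  list(next_state = tgt, reward = 0, goal_reached = FALSE)
}

#' Build an open rectangular arena
#'
#' Wall-free maze with the default layout used throughout: start and goal at
#' mid-height near the opposite short ends (start in column 3, goal in the
#' third column from the right).
#'
#' @param rows,cols arena dimensions.
#' @param start,goal optional `c(row, col)` overrides.
#' @param step_cap trial step cap (default 5000).
#' @return A [grid_maze()].
#' @export
make_open_arena <- function(rows, cols, start = NULL, goal = NULL,
                            step_cap = 5000) {
  rows <- as.integer(rows)
  cols <- as.integer(cols)
  if (is.null(start)) start <- c(rows %/% 2L + 1L, min(3L, cols))
  if (is.null(goal)) goal <- c(rows %/% 2L + 1L, max(cols - 2L, 1L))
  grid_maze(rows, cols, NULL, start, goal, step_cap = step_cap)
}

#' Scale the reference arena by a factor
#'
#' Produces an open arena of `(base_rows * factor) x (base_cols * factor)`
#' with start and goal rescaled proportionally (the default mid-height
#' placement applied to the scaled grid). The step cap grows with the factor.
#'
#' @param base_rows,base_cols base dimensions (default 16 x 48).
#' @param factor scale factor; must yield integer dimensions.
#' @param step_cap trial cap; default `round(5000 * factor)`.
#' @return A [grid_maze()].
#' @export
scale_arena <- function(base_rows = 16, base_cols = 48, factor = 1,
                        step_cap = NULL) {
  rows <- base_rows * factor
  cols <- base_cols * factor
  if (abs(rows - round(rows)) > 1e-9 || abs(cols - round(cols)) > 1e-9)
    stop("factor must yield integer dimensions", call. = FALSE)
  if (is.null(step_cap)) step_cap <- round(5000 * factor)
  make_open_arena(as.integer(round(rows)), as.integer(round(cols)),
                  step_cap = as.integer(step_cap))
}

#' Boundary-adaptation mazes
#'
#' Five 16 x 48 mazes, each the open arena plus internal boundary walls that
#' force a detour through the route learned in the open arena. Start and goal
#' match `make_open_arena(16, 48)`. Shipped as ASCII fixtures.
#'
#' @param variant one of `"A"`..`"E"`.
#' @return A [grid_maze()].
#' @export
make_adaptation_maze <- function(variant = c("A", "B", "C", "D", "E")) {
  variant <- match.arg(variant)
  path <- system.file("extdata", paste0("adapt_", variant, ".txt"),
                      package = "hipporl", mustWork = TRUE)
  m <- read_maze(readLines(path))
  m$step_cap <- 5000L
  m
}

#' Four-goal probabilistic-reward arena
#'
#' A 7 x 7 open arena with four candidate reward sites in the corners and the
#' start at the centre. In the context-switching task the reward is placed at
#' one of the four sites each trial; the maze's `goal` field holds site 1 and
#' the full site list is in `attr(maze, "reward_sites")` (4 x 2 matrix).
#'
#' @return A [grid_maze()] with a `reward_sites` attribute.
#' @export
make_four_goal_maze <- function() {
  m <- grid_maze(7, 7, NULL, start = c(4, 4), goal = c(1, 1), step_cap = 500)
  attr(m, "reward_sites") <- rbind(c(1, 1), c(1, 7), c(7, 1), c(7, 7))
  m
}

#' Read and write mazes as ASCII text
#'
#' The format is one row per line: `#` wall, `.` free, `S` start, `G` goal.
#' `read_maze(write_maze(m))` reproduces `m`'s geometry.
#'
#' @param text character vector of lines, or one string with embedded
#'   newlines.
#' @return `read_maze()`: a [grid_maze()]; `write_maze()`: a single string.
#' @export
read_maze <- function(text) {
  if (length(text) == 1L && grepl("\n", text))
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  text <- text[nzchar(text)]
  if (length(text) < 2L) stop("maze text needs at least 2 rows", call. = FALSE)
  widths <- nchar(text)
  if (length(unique(widths)) != 1L)
    stop("ragged rows in maze text", call. = FALSE)
  ch <- do.call(rbind, strsplit(text, "", fixed = TRUE))
  bad <- setdiff(unique(as.vector(ch)), c("#", ".", "S", "G"))
  if (length(bad))
    stop("invalid maze characters: ", paste(bad, collapse = " "), call. = FALSE)
  locate <- function(sym) {
    w <- which(ch == sym, arr.ind = TRUE)
    if (nrow(w) != 1L)
      stop("maze text must contain exactly one '", sym, "'", call. = FALSE)
    as.integer(w[1, ])
  }
  start <- locate("S")
  goal <- locate("G")
  grid_maze(nrow(ch), ncol(ch), ch == "#", start, goal)
}

#' @rdname read_maze
#' @param maze a [grid_maze()].
#' @export
write_maze <- function(maze) {
  ch <- matrix(".", maze$rows, maze$cols)
  ch[maze$walls] <- "#"
  ch[maze$start[1], maze$start[2]] <- "S"
  ch[maze$goal[1], maze$goal[2]] <- "G"
  paste(apply(ch, 1, paste, collapse = ""), collapse = "\n")
}

#' Check that the goal is reachable from the start
#'
#' Breadth-first flood fill over free cells; used to validate maze fixtures.
#'
#' @param maze a [grid_maze()].
#' @return `TRUE` if a path start -> goal exists.
#' @export
maze_connected <- function(maze) {
  n <- maze$rows * maze$cols
  free <- !t(maze$walls) # row-major order
  seen <- rep(FALSE, n)
  q <- cell_id(maze, maze$start)
  seen[q] <- TRUE
  gid <- cell_id(maze, maze$goal)
  while (length(q)) {
    s <- q[1]
    q <- q[-1]
    if (s == gid) return(TRUE)
    r <- (s - 1L) %/% maze$cols
    c <- (s - 1L) %% maze$cols
    for (a in 1:4) {
      nr <- r + c(-1L, 1L, 0L, 0L)[a]
      nc <- c + c(0L, 0L, -1L, 1L)[a]
      if (nr < 0L || nr >= maze$rows || nc < 0L || nc >= maze$cols) next
      id <- nr * maze$cols + nc + 1L
      if (!seen[id] && free[id]) {
        seen[id] <- TRUE
        q <- c(q, id)
      }
    }
  }
  FALSE
}

# 0-based payload handed to the C++ engine
maze_to_cpp <- function(maze) {
  list(rows = maze$rows, cols = maze$cols,
       start0 = cell_id(maze, maze$start) - 1L,
       goal0 = cell_id(maze, maze$goal) - 1L,
       goal_reward = maze$goal_reward, wall_penalty = maze$wall_penalty,
       step_cap = maze$step_cap,
       wall0 = as.integer(t(maze$walls)))
}
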