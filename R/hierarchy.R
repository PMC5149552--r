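#' Build the spatial abstraction hierarchy for a maze
#'
#' Level 1 is the maze grid itself. Each higher level aggregates 2 x 2 blocks
#' of the level below (partial blocks at the right/bottom edges); once a
#' dimension collapses to 1, groups of four along the remaining dimension are
#' aggregated instead. Construction stops at a single macro-state. A 16 x 48
#' maze yields six levels with 768, 192, 48, 12, 3 and 1 states.
#'
#' @param maze a [grid_maze()], or `c(rows, cols)`.
#' @return list of levels; each has `rows`, `cols`, `n`, and for levels above
#'   the first an `up` integer vector mapping each state of the level below
#'   to its macro-state (1-based, row-major ids).
#' @export
build_hierarchy <- function(maze) {
  if (inherits(maze, "grid_maze")) {
    rows <- maze$rows
    cols <- maze$cols
  } else {
    rows <- as.integer(maze[1])
    cols <- as.integer(maze[2])
  }
  levels <- list(list(rows = rows, cols = cols, n = rows * cols))
  repeat {
    cur <- levels[[length(levels)]]
    if (cur$n == 1L) break
    if (cur$rows > 1L && cur$cols > 1L) {
      br <- 2L
      bc <- 2L
    } else if (cur$rows == 1L) {
      br <- 1L
      bc <- 4L
    } else {
      br <- 4L
      bc <- 1L
    }
    nr <- ceiling(cur$rows / br)
    nc <- ceiling(cur$cols / bc)
    # row-major map: state of the level below -> macro-state above
    s <- seq_len(cur$n) - 1L
    r <- s %/% cur$cols
    c <- s %% cur$cols
    up <- (r %/% br) * nc + (c %/% bc) + 1L
    levels[[length(levels) + 1L]] <-
      list(rows = as.integer(nr), cols = as.integer(nc),
           n = as.integer(nr * nc), up = as.integer(up))
  }
  levels
}

#' Per-level discount schedule
#'
#' Discounts decrease linearly with abstraction level, from `high` at the
#' base to `low` at the top, so that higher levels prefer immediate reward
#' and no single level dominates goal selection. With one level the base
#' discount is used.
#'
#' @param n_levels number of levels.
#' @param high,low base-level and top-level discounts (defaults 0.9, 0.5).
#' @return numeric vector of length `n_levels`.
#' @export
discount_schedule <- function(n_levels, high = 0.9, low = 0.5) {
  if (n_levels == 1L) return(high)
  seq(high, low, length.out = n_levels)
}
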