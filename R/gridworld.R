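# Maze representation, geometry and action feasibility.
#
# A maze lives on a width x height grid of cells addressed by 0-based
# (x, y) with x increasing east and y increasing north. Internally cells
# are also referred to by their 1-based linear index x + y*width + 1.

ACTIONS <- c("N", "E", "S", "W")
ACTION_DX <- c(N = 0L, E = 1L, S = 0L, W = -1L)
ACTION_DY <- c(N = 1L, E = 0L, S = -1L, W = 0L)

CONDITIONS <- c("visual_haptic", "haptic", "navigation")

.cond_code <- function(condition) {
  match(match.arg(condition, CONDITIONS), CONDITIONS) - 1L
}

#' Construct a maze
#'
#' @param blocked Logical (or 0/1) matrix of dimension `width x height`,
#'   indexed as `blocked[x + 1, y + 1]` with `TRUE` for cells filled by a
#'   maze block.
#' @param starts Integer matrix with columns x, y (0-based), one row per
#'   trial start location, in trial order.
#' @param target Length-2 integer vector `c(x, y)`, the single target cell.
#' @param id Character identifier.
#'
#' @return An object of class `maze` with fields `width`, `height`,
#'   `blocked`, `starts`, `target`, `id`.
#' @export
maze <- function(blocked, starts, target, id = "maze") {
  blocked <- as.matrix(blocked)
  storage.mode(blocked) <- "logical"
  width <- nrow(blocked)
  height <- ncol(blocked)
  starts <- matrix(as.integer(starts), ncol = 2,
                   dimnames = list(NULL, c("x", "y")))
  target <- as.integer(target)
  m <- structure(list(width = width, height = height, blocked = blocked,
                      starts = starts, target = target,
                      id = as.character(id)),
                 class = "maze")
  in_b <- function(xy) all(xy[, 1] >= 0 & xy[, 1] < width &
                           xy[, 2] >= 0 & xy[, 2] < height)
  if (!in_b(matrix(target, ncol = 2)))
    stop("target out of bounds")
  if (!in_b(starts))
    stop("start location out of bounds")
  if (blocked[target[1] + 1, target[2] + 1])
    stop("target cell is blocked")
  if (any(blocked[cbind(starts[, 1] + 1, starts[, 2] + 1)]))
    stop("a start cell is blocked")
  if (any(starts[, 1] == target[1] & starts[, 2] == target[2]))
    stop("a start coincides with the target")
  m
}

#' @export
print.maze <- function(x, ...) {
  cat(sprintf("maze '%s' (%dx%d), %d blocks, %d starts, target (%d,%d)\n",
              x$id, x$width, x$height, sum(x$blocked), nrow(x$starts),
              x$target[1], x$target[2]))
  invisible(x)
}

#' Build a maze from character rows
#'
#' Convenience constructor for fixtures: `rows` are given north to south,
#' one string per grid row, with `#` for a block, `T` for the target, `S`
#' for start cells (in reading order unless `starts` is supplied) and any
#' other character for open space.
#'
#' @param rows Character vector of equal-length strings, listed north first.
#' @param starts,target Optional explicit locations (as in [maze()]).
#' @param id Maze identifier.
#' @return A `maze`.
#' @export
maze_from_text <- function(rows, starts = NULL, target = NULL, id = "maze") {
  chars <- do.call(rbind, strsplit(rows, ""))
  height <- nrow(chars)
  width <- ncol(chars)
  blocked <- matrix(FALSE, width, height)
  found_starts <- NULL
  for (r in seq_len(height)) {
    y <- height - r # row 1 is the north edge
    for (cix in seq_len(width)) {
      x <- cix - 1
      ch <- chars[r, cix]
      if (ch == "#") blocked[x + 1, y + 1] <- TRUE
      if (ch == "T" && is.null(target)) target <- c(x, y)
      if (ch == "S") found_starts <- rbind(found_starts, c(x, y))
    }
  }
  if (is.null(starts)) starts <- found_starts
  maze(blocked, starts, target, id = id)
}

#' Linear cell index of (x, y) locations
#'
#' @param m A `maze` (or any list with `width`, `height`).
#' @param xy Integer matrix with columns x, y (0-based), or a length-2
#'   vector.
#' @return 1-based linear indices `x + y*width + 1`.
#' @export
cell_index <- function(m, xy) {
  xy <- matrix(as.integer(xy), ncol = 2)
  if (any(xy[, 1] < 0 | xy[, 1] >= m$width | xy[, 2] < 0 |
          xy[, 2] >= m$height))
    stop("cell out of bounds")
  xy[, 1] + xy[, 2] * m$width + 1L
}

#' Inverse of [cell_index()]
#' @param m A `maze`.
#' @param idx 1-based linear indices.
#' @return Integer matrix with columns x, y.
#' @export
cell_xy <- function(m, idx) {
  idx <- as.integer(idx) - 1L
  cbind(x = idx %% m$width, y = idx %/% m$width)
}

.blocked_vec <- function(m) as.vector(m$blocked)

.is_blocked <- function(m, xy) m$blocked[xy[1] + 1, xy[2] + 1]

#' Actions that stay inside the grid
#'
#' All actions whose intended cell lies inside the maze boundary,
#' regardless of blocks, in the canonical order N, E, S, W.
#'
#' @param m A `maze`.
#' @param s Length-2 vector `c(x, y)`, 0-based.
#' @return Character vector, a subset of `c("N","E","S","W")`.
#' @export
in_bounds_actions <- function(m, s) {
  s <- as.integer(s)
  if (s[1] < 0 || s[1] >= m$width || s[2] < 0 || s[2] >= m$height)
    stop("state out of bounds")
  nx <- s[1] + ACTION_DX
  ny <- s[2] + ACTION_DY
  ACTIONS[nx >= 0 & nx < m$width & ny >= 0 & ny < m$height]
}

#' Actions leading to reachable (open) states
#'
#' The subset of [in_bounds_actions()] whose intended cell is not blocked.
#' A fully walled-in state yields an empty set with a warning, since no
#' executed step can originate there.
#'
#' @inheritParams in_bounds_actions
#' @return Character vector of actions.
#' @export
reachable_actions <- function(m, s) {
  s <- as.integer(s)
  if (.is_blocked(m, s)) stop("state is blocked")
  acts <- in_bounds_actions(m, s)
  nx <- s[1] + ACTION_DX[acts]
  ny <- s[2] + ACTION_DY[acts]
  out <- acts[!m$blocked[cbind(nx + 1, ny + 1)]]
  if (length(out) == 0)
    warning(sprintf("state (%d,%d) is fully walled in", s[1], s[2]))
  out
}

#' Manhattan distance between cells
#'
#' @param s,t Cells as length-2 vectors `c(x, y)` or matrices with columns
#'   x, y (recycled row-wise).
#' @return Integer vector of |dx| + |dy| distances.
#' @export
manhattan <- function(s, t) {
  s <- matrix(as.integer(s), ncol = 2)
  t <- matrix(as.integer(t), ncol = 2)
  as.integer(abs(s[, 1] - t[, 1]) + abs(s[, 2] - t[, 2]))
}

# Breadth-first distances (in open 4-connected steps) from the target to
# every cell; Inf where unreachable or blocked.
.bfs_dist <- function(m, from = NULL) {
  n <- m$width * m$height
  blk <- .blocked_vec(m)
  if (is.null(from)) from <- cell_index(m, m$target)
  dist <- rep(Inf, n)
  dist[from] <- 0
  queue <- from
  W <- m$width
  H <- m$height
  while (length(queue) > 0) {
    cur <- queue[1]
    queue <- queue[-1]
    x <- (cur - 1L) %% W
    y <- (cur - 1L) %/% W
    for (a in 1:4) {
      nx <- x + ACTION_DX[a]
      ny <- y + ACTION_DY[a]
      if (nx < 0 || nx >= W || ny < 0 || ny >= H) next
      nb <- nx + ny * W + 1L
      if (blk[nb] || is.finite(dist[nb])) next
      dist[nb] <- dist[cur] + 1
      queue <- c(queue, nb)
    }
  }
  dist
}

#' Shortest open path length from each start to the target
#'
#' @param m A `maze`.
#' @return Numeric vector, one entry per start row (Inf if unreachable).
#' @export
shortest_path_lengths <- function(m) {
  d <- .bfs_dist(m)
  d[cell_index(m, m$starts)]
}

#' Validate a maze
#'
#' Checks that the target is reachable from every start through open
#' 4-connected cells (breadth-first flood fill).
#'
#' @param m A `maze`.
#' @return A list of class `maze_validation` with `valid` (logical),
#'   `unreachable_starts` (matrix of x, y rows) and `distances` (shortest
#'   path length per start).
#' @export
validate_maze <- function(m) {
  if (!inherits(m, "maze")) stop("malformed maze object")
  d <- shortest_path_lengths(m)
  bad <- !is.finite(d)
  structure(list(valid = !any(bad),
                 unreachable_starts = m$starts[bad, , drop = FALSE],
                 distances = d),
            class = "maze_validation")
}

#' @export
print.maze_validation <- function(x, ...) {
  if (x$valid) cat("maze valid: target reachable from all starts\n")
  else cat(sprintf("maze INVALID: %d unreachable start(s)\n",
                   nrow(x$unreachable_starts)))
  invisible(x)
}
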