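# Model-based learner: transition beliefs, reward function, offline value
# iteration, and Boltzmann action selection.
#
# The transition belief T is an n_cells x 4 matrix (columns N, E, S, W);
# T[s, a] is the believed probability that the cell intended by action a
# from cell s is reachable. Pairs leading off-grid are fixed at 0.

.succ_index <- function(m, s_idx, a) {
  # 1-based successor index or NA off-grid, vectorized over s_idx
  xy <- cell_xy(m, s_idx)
  nx <- xy[, 1] + ACTION_DX[a]
  ny <- xy[, 2] + ACTION_DY[a]
  ok <- nx >= 0 & nx < m$width & ny >= 0 & ny < m$height
  out <- rep(NA_integer_, length(s_idx))
  out[ok] <- nx[ok] + ny[ok] * m$width + 1L
  out
}

#' True (binary) transition function of a maze
#'
#' @param m A `maze`.
#' @return n x 4 matrix with 1 where the intended cell is open and
#'   in-bounds, 0 otherwise.
#' @export
true_transition <- function(m) {
  n <- m$width * m$height
  blk <- .blocked_vec(m)
  T <- matrix(0, n, 4, dimnames = list(NULL, ACTIONS))
  for (a in ACTIONS) {
    sp <- .succ_index(m, seq_len(n), a)
    ok <- !is.na(sp)
    T[ok, a] <- as.numeric(!blk[sp[ok]])
  }
  T
}

#' Initialize the transition belief for a condition
#'
#' Visual-Haptic agents read the layout from the visible map, giving the
#' binary true transition function. Haptic and navigation agents start
#' from a uniform prior reachability `p0` on all in-bounds pairs (0 on
#' pairs leading off-grid) and learn from interaction events.
#'
#' @param condition One of `"visual_haptic"`, `"haptic"`, `"navigation"`.
#' @param m A `maze`.
#' @param p0 Prior reachability in (0, 1); required unless
#'   `condition == "visual_haptic"`.
#' @return n x 4 transition matrix.
#' @export
init_transition <- function(condition, m, p0 = NULL) {
  condition <- match.arg(condition, CONDITIONS)
  if (condition == "visual_haptic") return(true_transition(m))
  if (is.null(p0)) stop("p0 is required for the ", condition, " condition")
  if (p0 <= 0 || p0 >= 1) stop("p0 must be in (0,1)")
  n <- m$width * m$height
  T <- matrix(0, n, 4, dimnames = list(NULL, ACTIONS))
  for (a in ACTIONS) {
    sp <- .succ_index(m, seq_len(n), a)
    T[!is.na(sp), a] <- p0
  }
  T
}

#' Update the transition belief from one interaction event
#'
#' Every in-bounds state-action pair leading into the interacted cell
#' `s_prime` (up to four) moves toward the observation `h` by fraction
#' `alpha`: `T(s,a) <- T(s,a) + alpha * (h - T(s,a))`.
#'
#' @param T n x 4 transition matrix.
#' @param m A `maze`.
#' @param s_prime The interacted cell, `c(x, y)` (entered: `h = 1`;
#'   contacted block: `h = 0`).
#' @param h Observation, 0 or 1.
#' @param alpha Learning rate in (0, 1).
#' @return Updated transition matrix.
#' @export
update_transition <- function(T, m, s_prime, h, alpha) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0,1)")
  sp <- as.integer(s_prime)
  for (a in seq_along(ACTIONS)) {
    # neighbour on side a of s_prime acts with the opposite action
    qx <- sp[1] + ACTION_DX[a]
    qy <- sp[2] + ACTION_DY[a]
    if (qx < 0 || qx >= m$width || qy < 0 || qy >= m$height) next
    q <- qx + qy * m$width + 1L
    opp <- (a + 1L) %% 4L + 1L # N<->S, E<->W
    T[q, opp] <- T[q, opp] + alpha * (h - T[q, opp])
  }
  T
}

#' Visibility update for the navigation task
#'
#' On the first step of a trial the whole 3 x 3 neighbourhood centred on
#' the current cell is observed (the participant looks around); on later
#' steps the three cells one step beyond the newly entered cell in the
#' heading direction (front-left, front-centre, front-right) are observed.
#' Each observed in-bounds cell updates the belief toward its true
#' occupancy via [update_transition()].
#'
#' @param T n x 4 transition matrix.
#' @param m A `maze`.
#' @param s Current (newly entered) cell `c(x, y)`.
#' @param heading Action name giving the direction of the most recent
#'   executed step; may be `NULL` on the first step of a trial.
#' @param first_step Logical; first step of the trial?
#' @param alpha Learning rate.
#' @return Updated transition matrix.
#' @export
navigation_visibility_update <- function(T, m, s, heading = NULL,
                                         first_step = FALSE, alpha) {
  s <- as.integer(s)
  cells <- NULL
  if (first_step) {
    for (dx in -1:1) for (dy in -1:1)
      cells <- rbind(cells, c(s[1] + dx, s[2] + dy))
  } else {
    if (is.null(heading))
      stop("heading is required after the first step of a trial")
    dx <- ACTION_DX[[heading]]; dy <- ACTION_DY[[heading]]
    px <- dy; py <- dx # perpendicular flank offset
    for (k in -1:1)
      cells <- rbind(cells, c(s[1] + dx + k * px, s[2] + dy + k * py))
  }
  for (i in seq_len(nrow(cells))) {
    cx <- cells[i, 1]; cy <- cells[i, 2]
    if (cx < 0 || cx >= m$width || cy < 0 || cy >= m$height) next
    h <- as.numeric(!m$blocked[cx + 1, cy + 1])
    T <- update_transition(T, m, c(cx, cy), h, alpha)
  }
  T
}

#' Offline value iteration
#'
#' Solves `V(s) <- max_a T(s,a) [R(s,a) + gamma V(s')]` by synchronous
#' Bellman sweeps until the sup-norm change falls below `tol`. The reward
#' function is implied by the maze: `R(s,a) = 1` iff action a from s leads
#' to the target. The target is treated as terminating: its outgoing pairs
#' are masked to 0 on a planning-time copy of `T`, so `V(target) = 0`.
#'
#' @param m A `maze`.
#' @param T n x 4 transition matrix; defaults to the true transition
#'   function.
#' @param gamma Temporal discount in (0, 1).
#' @param tol Sup-norm convergence tolerance.
#' @param max_iter Maximum number of sweeps; non-convergence is an error
#'   reporting the residual.
#' @param V0 Optional initial value vector (defaults to zero).
#' @return Numeric vector of values, one per cell, with attributes
#'   `iterations`, `residual` and `residual_trace`.
#' @export
value_iteration <- function(m, T = NULL, gamma, tol = 1e-6,
                            max_iter = 1000L, V0 = NULL) {
  if (is.null(T)) T <- true_transition(m)
  n <- m$width * m$height
  if (is.null(V0)) V0 <- numeric(n)
  res <- cpp_value_iteration(T, m$width, m$height, cell_index(m, m$target),
                             gamma, tol, as.integer(max_iter), V0)
  if (!res$converged)
    stop(sprintf("value iteration did not converge in %d sweeps (residual %g)",
                 max_iter, res$residual))
  structure(res$V, iterations = res$iterations, residual = res$residual,
            residual_trace = res$residual_trace)
}

.action_values_mb <- function(m, T, V, s, gamma) {
  s_idx <- cell_index(m, matrix(s, ncol = 2))
  tgt <- cell_index(m, m$target)
  vals <- setNames(numeric(4), ACTIONS)
  for (a in ACTIONS) {
    sp <- .succ_index(m, s_idx, a)
    if (is.na(sp)) { vals[a] <- NA; next }
    r <- as.numeric(sp == tgt)
    v <- if (sp == tgt) 0 else V[sp]
    vals[a] <- T[s_idx, a] * (r + gamma * v)
  }
  vals
}

#' Model-based Boltzmann policy
#'
#' Softmax with temperature `tau` over the action values
#' `T(s,a) [R(s,a) + gamma V(s')]`, renormalized over the supplied action
#' set (in-bounds actions during simulation, reachable actions during
#' fitting).
#'
#' @param m A `maze`.
#' @param T n x 4 transition matrix.
#' @param V Value vector from [value_iteration()].
#' @param s Cell `c(x, y)`.
#' @param gamma Discount used for planning.
#' @param tau Boltzmann temperature > 0.
#' @param actions Action set; defaults to [reachable_actions()].
#' @return Named probability vector over `actions` summing to 1.
#' @export
mb_policy <- function(m, T, V, s, gamma, tau, actions = NULL) {
  if (tau <= 0) stop("tau must be > 0")
  if (is.null(actions)) actions <- reachable_actions(m, s)
  if (length(actions) == 0) stop("empty action set")
  vals <- .action_values_mb(m, T, V, s, gamma)[actions]
  e <- exp((vals - max(vals)) / tau)
  e / sum(e)
}

#' Per-cell maximum action value map
#'
#' The highest model-based action value among all in-bounds actions in
#' each state, as plotted in value-map figures.
#'
#' @param m A `maze`.
#' @param T n x 4 transition matrix.
#' @param gamma Discount.
#' @param ... Passed to [value_iteration()].
#' @return `width x height` matrix (indexed `[x+1, y+1]`).
#' @export
mb_value_map <- function(m, T = NULL, gamma, ...) {
  if (is.null(T)) T <- true_transition(m)
  V <- value_iteration(m, T, gamma, ...)
  n <- m$width * m$height
  out <- numeric(n)
  for (s in seq_len(n))
    out[s] <- max(.action_values_mb(m, T, V, cell_xy(m, s), gamma),
                  na.rm = TRUE)
  matrix(out, m$width, m$height)
}

#' Write a value map as a CSV grid
#'
#' Rows are written north to south so the file reads like the maze seen
#' from above.
#'
#' @param map `width x height` matrix from [mb_value_map()] or
#'   [mf_value_map()].
#' @param path Output file.
#' @export
write_value_map <- function(map, path) {
  grid <- t(map)[rev(seq_len(ncol(map))), , drop = FALSE]
  write.table(grid, path, sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(path)
}
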