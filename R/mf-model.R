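# Model-free Q(lambda) learner: cached action values with eligibility
# traces, pessimistic (all-zero) initialization, Boltzmann selection.
#
# Q and the trace e are n_cells x 4 matrices (columns N, E, S, W). The
# learner has no transition model: block-contact events never touch Q or
# the trace; only executed grid transitions count.

#' Zero-initialized Q-function (or trace) for a maze
#'
#' @param m A `maze`.
#' @return n x 4 zero matrix with action column names.
#' @export
init_q <- function(m) {
  matrix(0, m$width * m$height, 4, dimnames = list(NULL, ACTIONS))
}

#' One Q(lambda) update from an executed transition
#'
#' The trace first decays by `gamma * lambda` everywhere and gains +1 at
#' the taken pair; a single scalar reward-prediction error
#' `delta = r + gamma max_a' Q(s_next, a') - Q(s, a)` is then applied to
#' every pair in proportion to its trace. The max at `s_next` ranges over
#' all four in-bounds actions (the belief-free learner cannot exclude
#' blocked moves).
#'
#' @param Q,e n x 4 value and trace matrices.
#' @param m A `maze`.
#' @param s Current cell `c(x, y)`.
#' @param a Executed action name.
#' @param r Immediate reward (1 iff the target was entered).
#' @param s_next Entered cell `c(x, y)`.
#' @param params List with `alpha`, `gamma`, `lambda` in (0, 1).
#' @return List with updated `Q` and `e`.
#' @export
update_q <- function(Q, e, m, s, a, r, s_next, params) {
  stopifnot(params$alpha > 0, params$alpha < 1)
  e <- e * (params$gamma * params$lambda)
  s_idx <- cell_index(m, matrix(as.integer(s), ncol = 2))
  e[s_idx, a] <- e[s_idx, a] + 1
  nb <- in_bounds_actions(m, s_next)
  next_idx <- cell_index(m, matrix(as.integer(s_next), ncol = 2))
  delta <- r + params$gamma * max(Q[next_idx, nb]) - Q[s_idx, a]
  Q <- Q + params$alpha * delta * e
  list(Q = Q, e = e)
}

#' Model-free Boltzmann policy
#'
#' Softmax with temperature `tau` directly over cached Q values,
#' renormalized over the supplied action set.
#'
#' @param Q n x 4 Q matrix.
#' @param m A `maze`.
#' @param s Cell `c(x, y)`.
#' @param tau Temperature > 0.
#' @param actions Action set; defaults to [reachable_actions()].
#' @return Named probability vector over `actions`.
#' @export
mf_policy <- function(Q, m, s, tau, actions = NULL) {
  if (tau <= 0) stop("tau must be > 0")
  if (is.null(actions)) actions <- reachable_actions(m, s)
  if (length(actions) == 0) stop("empty action set")
  q <- Q[cell_index(m, matrix(as.integer(s), ncol = 2)), actions]
  e <- exp((q - max(q)) / tau)
  e / sum(e)
}

#' Maze-boundary reset of the Q-function
#'
#' In "reset" carryover mode (the default, which fits behaviour better)
#' the Q-function is cleared at each new maze; in "running" mode it is
#' inherited across mazes. The eligibility trace is always cleared at the
#' start of every trial, by [reset_for_new_trial()].
#'
#' @param Q n x 4 Q matrix.
#' @param carryover `"reset"` or `"running"`.
#' @return Q matrix for the new maze.
#' @export
reset_for_new_maze <- function(Q, carryover = c("reset", "running")) {
  carryover <- match.arg(carryover)
  if (carryover == "reset") Q[] <- 0
  Q
}

#' Trial-boundary reset of the eligibility trace
#'
#' @param e n x 4 trace matrix.
#' @return Zeroed trace.
#' @export
reset_for_new_trial <- function(e) {
  e[] <- 0
  e
}

#' Per-cell maximum cached value map
#'
#' @param Q n x 4 Q matrix.
#' @param m A `maze`.
#' @return `width x height` matrix of `max_a Q(s, a)` over in-bounds
#'   actions.
#' @export
mf_value_map <- function(Q, m) {
  n <- m$width * m$height
  out <- numeric(n)
  for (s in seq_len(n)) {
    nb <- in_bounds_actions(m, cell_xy(m, s))
    out[s] <- max(Q[s, nb])
  }
  matrix(out, m$width, m$height)
}
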