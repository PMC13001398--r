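# Teacher-forced replay: evolve a learner through a participant's
# recorded events and return the probability each model assigns to the
# executed action at every step.

# Pack one participant's step records into the flat integer form consumed
# by the compiled replay cores. Mazes must share one grid size.
.pack_replay <- function(steps, mazes) {
  if (length(unique(steps$participant)) > 1)
    stop("step records span multiple participants; fit one at a time")
  cond <- unique(steps$condition)
  if (length(cond) > 1) stop("step records span multiple conditions")
  maze_ids <- unique(steps$maze)
  if (!all(maze_ids %in% names(mazes)))
    stop("step records reference unknown maze id(s)")
  mzs <- mazes[maze_ids]
  W <- mzs[[1]]$width
  H <- mzs[[1]]$height
  if (!all(vapply(mzs, function(m) m$width == W && m$height == H,
                  logical(1))))
    stop("mazes in one cohort must share a grid size")
  n <- W * H
  blocked <- vapply(mzs, function(m) as.integer(.blocked_vec(m)),
                    integer(n))
  target <- vapply(mzs, function(m) cell_index(m, m$target), integer(1))
  step_maze <- match(steps$maze, maze_ids)
  step_state <- steps$x + steps$y * W + 1L
  step_action <- match(steps$action, ACTIONS)
  contacts <- .parse_contacts(steps$contacts)
  contact_action <- match(unlist(contacts), ACTIONS)
  if (is.null(contact_action)) contact_action <- integer(0)
  contact_ptr <- c(0L, cumsum(lengths(contacts)))
  block_key <- paste(steps$participant, steps$maze)
  new_maze <- c(TRUE, block_key[-1] != block_key[-length(block_key)])
  trial_key <- paste(block_key, steps$trial)
  new_trial <- c(TRUE, trial_key[-1] != trial_key[-length(trial_key)])
  list(W = W, H = H, blocked = blocked, target = target,
       step_maze = as.integer(step_maze),
       step_state = as.integer(step_state),
       step_action = as.integer(step_action),
       new_trial = new_trial, new_maze = new_maze,
       contact_action = as.integer(contact_action),
       contact_ptr = as.integer(contact_ptr),
       trial = as.integer(steps$trial),
       condition = cond)
}

# Replay on pre-packed data; the packing above is the expensive R-side
# step, so fitting loops pack once and call this directly.
.replay_packed <- function(model, params, pk, reach_only = TRUE,
                           carryover = "reset", tol = 1e-6,
                           max_iter = 1000L) {
  cond_code <- .cond_code(pk$condition)
  if (model == "mb") {
    if (cond_code != 0L && (is.null(params$alpha) || is.null(params$p0)))
      stop("alpha and p0 are required for MB in the ", pk$condition,
           " condition")
    cpp_replay_mb(pk$W, pk$H, pk$blocked, pk$target, pk$step_maze,
                  pk$step_state, pk$step_action, pk$new_trial, pk$new_maze,
                  pk$contact_action, pk$contact_ptr, cond_code,
                  if (cond_code == 0L) 0 else params$alpha, params$gamma,
                  if (cond_code == 0L) 0 else params$p0, params$tau,
                  tol, as.integer(max_iter), reach_only)
  } else {
    cpp_replay_mf(pk$W, pk$H, pk$blocked, pk$target, pk$step_maze,
                  pk$step_state, pk$step_action, pk$new_trial, pk$new_maze,
                  params$alpha, params$gamma, params$lambda, params$tau,
                  carryover == "reset", reach_only)
  }
}

#' Per-step action probabilities of a learner along recorded behaviour
#'
#' Replays one participant's step records teacher-forced: the learner's
#' beliefs are updated from the participant's own events (block contacts,
#' then the executed transition, in recorded order), and at every step
#' the probability the learner assigns to the executed action is
#' returned. For the model-based learner, planning by value iteration is
#' (re)run whenever the transition belief has changed since the last
#' plan.
#'
#' @param model `"mb"` or `"mf"`.
#' @param params Named list of parameters. MB: `gamma`, `tau` always;
#'   `alpha`, `p0` in the haptic and navigation conditions. MF: `alpha`,
#'   `gamma`, `lambda`, `tau`.
#' @param steps Step records for a single participant and condition.
#' @param mazes Named list of `maze` objects.
#' @param reach_only If `TRUE` (fitting convention) probabilities are
#'   renormalized over actions leading to reachable states; if `FALSE`
#'   over all in-bounds actions.
#' @param carryover MF Q-function carryover across mazes (`"reset"` or
#'   `"running"`).
#' @param tol,max_iter Value-iteration controls (MB only).
#' @return Numeric vector, one probability per step row.
#' @export
step_probabilities <- function(model = c("mb", "mf"), params, steps, mazes,
                               reach_only = TRUE,
                               carryover = c("reset", "running"),
                               tol = 1e-6, max_iter = 1000L) {
  model <- match.arg(model)
  carryover <- match.arg(carryover)
  pk <- .pack_replay(steps, mazes)
  .replay_packed(model, params, pk, reach_only = reach_only,
                 carryover = carryover, tol = tol, max_iter = max_iter)
}

# Number of reachable actions at each recorded step (random baseline).
.n_reachable <- function(steps, mazes) {
  vapply(seq_len(nrow(steps)), function(i) {
    m <- mazes[[steps$maze[i]]]
    length(reachable_actions(m, c(steps$x[i], steps$y[i])))
  }, integer(1))
}
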