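# Closed-loop autonomous simulation: the agent learns from outcomes of
# its own sampled actions. At each step an action is drawn from the
# policy over in-bounds actions; a draw into a block is recorded as a
# contact (updating the MB belief in learned-map conditions), the
# original distribution is renormalized over the remaining options and
# redrawn until an open cell is entered.

AGENT_MODELS <- c("mb", "mf", "hybrid", "random")

#' Construct an agent specification for simulation
#'
#' @param model One of `"mb"`, `"mf"`, `"hybrid"`, `"random"`.
#' @param condition Condition label governing the MB observation rules.
#' @param theta_mb,theta_mf Learner parameter lists (as in
#'   [step_probabilities()]); required when the corresponding learner is
#'   used.
#' @param w_trial Per-trial MF weight vector for hybrid agents (recycled
#'   to the number of trials).
#' @param mf_carryover Q-function carryover across mazes.
#' @return An `agent_spec` list.
#' @export
agent_spec <- function(model = c("mb", "mf", "hybrid", "random"),
                       condition, theta_mb = NULL, theta_mf = NULL,
                       w_trial = NULL, mf_carryover = "reset") {
  model <- match.arg(model)
  condition <- match.arg(condition, CONDITIONS)
  if (model %in% c("mb", "hybrid") && is.null(theta_mb))
    stop("theta_mb required")
  if (model %in% c("mf", "hybrid") && is.null(theta_mf))
    stop("theta_mf required")
  if (model == "hybrid" && is.null(w_trial)) stop("w_trial required")
  structure(list(model = model, condition = condition,
                 theta_mb = theta_mb, theta_mf = theta_mf,
                 w_trial = w_trial, mf_carryover = mf_carryover),
            class = "agent_spec")
}

#' Agent specification from a fitted model
#'
#' Single fits simulate with their fitted parameters; HC/HD fits use the
#' parametric weight schedule; HS fits (descriptive, not generative) use
#' the approximated generative version — a single average fitted MF
#' weight for all steps within each trial.
#'
#' @param fit An `rl_fit` or `hybrid_fit`.
#' @param n_trials Number of trials per maze (for weight schedules).
#' @return An `agent_spec`.
#' @export
as_agent <- function(fit, n_trials = 10L) {
  trials <- seq_len(n_trials)
  if (inherits(fit, "hybrid_fit")) {
    w <- switch(fit$weights$model,
                hc = rep(.sigma(fit$weights$b0), n_trials),
                hd = .sigma(fit$weights$b0 + fit$weights$b1 * trials),
                hs = as.numeric(tapply(fit$weights$w, fit$trial, mean))[
                  trials])
    agent_spec("hybrid", fit$condition, theta_mb = fit$theta_mb,
               theta_mf = fit$theta_mf, w_trial = w)
  } else if (fit$model == "mb") {
    agent_spec("mb", fit$condition, theta_mb = fit$params)
  } else {
    agent_spec("mf", fit$condition, theta_mf = fit$params)
  }
}

.agent_code <- function(model) match(model, AGENT_MODELS) - 1L

.starts_matrix <- function(mazes, n_trials) {
  vapply(mazes, function(m) {
    k <- nrow(m$starts)
    idx <- cell_index(m, m$starts)
    idx[((seq_len(n_trials) - 1L) %% k) + 1L]
  }, integer(n_trials))
}

.run_simulation <- function(agent, mazes, n_trials, max_steps, tol,
                            max_iter) {
  W <- mazes[[1]]$width
  H <- mazes[[1]]$height
  n <- W * H
  blocked <- vapply(mazes, function(m) as.integer(.blocked_vec(m)),
                    integer(n))
  target <- vapply(mazes, function(m) cell_index(m, m$target), integer(1))
  starts <- .starts_matrix(mazes, n_trials)
  tmb <- agent$theta_mb
  tmf <- agent$theta_mf
  w_trial <- if (is.null(agent$w_trial)) numeric(n_trials)
             else rep_len(agent$w_trial, n_trials)
  cpp_simulate(W, H, blocked, target, matrix(starts, nrow = n_trials),
               .cond_code(agent$condition), .agent_code(agent$model),
               if (is.null(tmb$alpha)) 0 else tmb$alpha,
               if (is.null(tmb$gamma)) 0.9 else tmb$gamma,
               if (is.null(tmb$p0)) 0 else tmb$p0,
               if (is.null(tmb$tau)) 1 else tmb$tau,
               if (is.null(tmf$alpha)) 0.5 else tmf$alpha,
               if (is.null(tmf$gamma)) 0.9 else tmf$gamma,
               if (is.null(tmf$lambda)) 0.5 else tmf$lambda,
               if (is.null(tmf$tau)) 1 else tmf$tau,
               identical(agent$mf_carryover, "reset") ||
                 is.null(agent$mf_carryover),
               w_trial, as.integer(max_steps), tol, as.integer(max_iter))
}

#' Simulate a single trial with a fresh agent
#'
#' Runs one closed-loop trial from `start` on `m`. The agent starts from
#' freshly initialized beliefs; use [simulate_experiment()] for learning
#' across trials and mazes.
#'
#' @param agent An `agent_spec`.
#' @param m A `maze`.
#' @param start Start cell `c(x, y)` (defaults to the maze's first
#'   start).
#' @param max_steps Step cap per trial (default 88).
#' @param tol,max_iter Value-iteration controls.
#' @return A list: `path` (matrix of visited x, y rows, start first),
#'   `actions`, `contacts` (list per step), `success`, `n_steps`.
#' @export
simulate_trial <- function(agent, m, start = NULL, max_steps = 88L,
                           tol = 1e-6, max_iter = 1000L) {
  if (is.null(start)) start <- m$starts[1, ]
  m1 <- m
  m1$starts <- matrix(as.integer(start), ncol = 2)
  res <- .run_simulation(agent, list(m1), n_trials = 1L, max_steps,
                         tol, max_iter)
  states <- res$step_state
  acts <- ACTIONS[res$step_action]
  last <- cell_xy(m, states[length(states)])
  final <- c(last[1] + ACTION_DX[[acts[length(acts)]]],
             last[2] + ACTION_DY[[acts[length(acts)]]])
  contacts <- lapply(seq_along(states), function(t)
    ACTIONS[res$contact_action[seq2(res$contact_ptr[t] + 1,
                                    res$contact_ptr[t + 1])]])
  list(path = rbind(cell_xy(m, states), final),
       actions = acts, contacts = contacts,
       success = as.logical(res$trial_success[1]),
       n_steps = res$trial_steps[1])
}

seq2 <- function(from, to) if (from > to) integer(0) else seq(from, to)

#' Simulate repeated experiments for one agent
#'
#' Runs `n_reps` independent simulated experiments (each a full pass over
#' the maze set, `n_trials` trials per maze, with learning carried
#' through as in the behavioural task) and returns per-trial outcomes and
#' optionally the full step records in the behavioural schema.
#'
#' @param agent An `agent_spec` (or a fit coercible via [as_agent()]).
#' @param mazes Named list of `maze` objects.
#' @param n_trials Trials per maze (default 10).
#' @param n_reps Independent repetitions (default 10).
#' @param max_steps Step cap per trial (default 88).
#' @param seed Optional seed.
#' @param record_steps Keep the step records of every repetition?
#' @param participant Participant label used in the step records.
#' @param tol,max_iter Value-iteration controls.
#' @return A `sim_summary`: `trials` data frame (rep, maze, trial,
#'   success, n_steps), optional `steps` records, `agent`, counts.
#' @export
simulate_experiment <- function(agent, mazes, n_trials = 10L,
                                n_reps = 10L, max_steps = 88L,
                                seed = NULL, record_steps = FALSE,
                                participant = "sim", tol = 1e-6,
                                max_iter = 1000L) {
  if (inherits(agent, c("rl_fit", "hybrid_fit")))
    agent <- as_agent(agent, n_trials)
  if (!is.null(seed)) set.seed(seed)
  maze_ids <- names(mazes)
  trials <- NULL
  steps <- NULL
  for (rep_i in seq_len(n_reps)) {
    res <- .run_simulation(agent, mazes, n_trials, max_steps, tol,
                           max_iter)
    trials <- rbind(trials, data.frame(
      rep = rep_i, maze = maze_ids[res$trial_maze],
      trial = res$trial_index, success = as.logical(res$trial_success),
      n_steps = res$trial_steps))
    if (record_steps) {
      W <- mazes[[1]]$width
      xy <- cell_xy(mazes[[1]], res$step_state)
      contacts <- vapply(seq_along(res$step_state), function(t)
        paste(ACTIONS[res$contact_action[
          seq2(res$contact_ptr[t] + 1, res$contact_ptr[t + 1])]],
          collapse = ""), character(1))
      steps <- rbind(steps, data.frame(
        participant = participant, condition = agent$condition,
        maze = maze_ids[res$step_maze], trial = res$step_trial,
        step = res$step_index, x = xy[, 1], y = xy[, 2],
        action = ACTIONS[res$step_action], contacts = contacts,
        duration = NA_real_, rep = rep_i))
    }
  }
  structure(list(trials = trials, steps = steps, agent = agent,
                 n_trials = n_trials, n_reps = n_reps,
                 max_steps = max_steps),
            class = "sim_summary")
}

#' @export
print.sim_summary <- function(x, ...) {
  cat(sprintf("simulation: %s agent, %d reps x %d mazes x %d trials\n",
              x$agent$model, x$n_reps,
              length(unique(x$trials$maze)), x$n_trials))
  cat(sprintf("  success rate %.3f, mean path length %.2f\n",
              mean(x$trials$success), mean(x$trials$n_steps)))
  invisible(x)
}

#' Random-walk baseline for maze-start pairs
#'
#' Monte-Carlo estimate of the success probability (within the step cap)
#' and expected path length of a uniform random agent with the
#' contact-resample rule and no learning.
#'
#' @param m A `maze`.
#' @param start Start cell `c(x, y)`; default runs every start row.
#' @param max_steps Step cap (default 88).
#' @param n_reps Monte-Carlo repetitions per start (default 1000).
#' @param seed Optional seed.
#' @return Data frame per start: `x`, `y`, `success_rate`, `success_se`,
#'   `mean_length`, `length_se`.
#' @export
random_baseline <- function(m, start = NULL, max_steps = 88L,
                            n_reps = 1000L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  starts <- if (is.null(start)) m$starts
            else matrix(as.integer(start), ncol = 2)
  out <- NULL
  blk <- as.integer(.blocked_vec(m))
  tgt <- cell_index(m, m$target)
  for (i in seq_len(nrow(starts))) {
    res <- cpp_random_baseline(m$width, m$height, blk, tgt,
                               cell_index(m, starts[i, , drop = FALSE]),
                               as.integer(max_steps), as.integer(n_reps))
    out <- rbind(out, data.frame(
      x = starts[i, 1], y = starts[i, 2],
      success_rate = mean(res$success),
      success_se = sd(res$success) / sqrt(n_reps),
      mean_length = mean(res$steps),
      length_se = sd(res$steps) / sqrt(n_reps)))
  }
  out
}

#' Scaled success and path-length indices
#'
#' Success rate is rescaled between random-agent performance (0) and
#' 100% success (1); path length between the shortest possible length
#' (0) and the expected random-agent length (1):
#' `success_index = (s - s_rand) / (1 - s_rand)`,
#' `path_index = (L - L_min) / (L_rand - L_min)`. Values outside
#' \[0, 1\] (an agent worse than random) are reported unclamped;
#' degenerate trials (`s_rand = 1` or `L_rand = L_min`) yield `NA` with
#' a warning.
#'
#' @param sim A `sim_summary` from [simulate_experiment()].
#' @param mazes The maze set simulated.
#' @param baseline_reps Monte-Carlo repetitions for the random baseline.
#' @param baseline_seed Seed for the baseline draws.
#' @return Data frame per trial position: success rate, mean path length,
#'   baseline values, shortest length, `success_index`, `path_index`.
#' @export
performance_indices <- function(sim, mazes, baseline_reps = 1000L,
                                baseline_seed = 1L) {
  n_trials <- sim$n_trials
  starts <- .starts_matrix(mazes, n_trials)
  # baseline and shortest length per (maze, trial position)
  base_succ <- matrix(NA_real_, n_trials, length(mazes))
  base_len <- matrix(NA_real_, n_trials, length(mazes))
  short_len <- matrix(NA_real_, n_trials, length(mazes))
  set.seed(baseline_seed)
  for (j in seq_along(mazes)) {
    m <- mazes[[j]]
    d <- .bfs_dist(m)
    for (tr in seq_len(n_trials)) {
      xy <- cell_xy(m, starts[tr, j])
      b <- random_baseline(m, xy, max_steps = sim$max_steps,
                           n_reps = baseline_reps)
      base_succ[tr, j] <- b$success_rate
      base_len[tr, j] <- b$mean_length
      short_len[tr, j] <- d[starts[tr, j]]
    }
  }
  trials <- sim$trials
  out <- NULL
  for (tr in seq_len(n_trials)) {
    sel <- trials$trial == tr
    s_obs <- mean(trials$success[sel])
    l_obs <- mean(trials$n_steps[sel])
    s_rand <- mean(base_succ[tr, ])
    l_rand <- mean(base_len[tr, ])
    l_min <- mean(short_len[tr, ])
    s_idx <- if (s_rand >= 1) NA_real_ else (s_obs - s_rand) / (1 - s_rand)
    p_idx <- if (l_rand <= l_min) NA_real_
             else (l_obs - l_min) / (l_rand - l_min)
    out <- rbind(out, data.frame(
      trial = tr, success_rate = s_obs, mean_length = l_obs,
      random_success = s_rand, random_length = l_rand,
      shortest_length = l_min, success_index = s_idx,
      path_index = p_idx))
  }
  if (anyNA(out$success_index) || anyNA(out$path_index))
    warning("degenerate trial position(s): index undefined, reported NA")
  out
}
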